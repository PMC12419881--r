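#' Assemble a mean-FLAME equation system
#'
#' Enumerates all occupation states (explicit coordinates plus one mean-field
#' sentinel per dimension with a limit) and all mean-field value equations,
#' and compiles a vectorised right-hand side implementing the boundary
#' semantics of the hybrid construction:
#' probability flows between explicit states follow the standard master
#' equation; an increment out of the last explicit state enters the limit;
#' a decrement of a dimension inside its limit exits to the last explicit
#' state at the boundary rate (the rate evaluated at the cutoff, times the
#' truncated-Poisson edge probability [rho()]); events that move another
#' dimension while decrementing a limited one split into an exit branch
#' (rate at the cutoff times rho) and a stay branch (rate at the mean-field
#' value times 1 - rho); events inside a limit that move only limited
#' dimensions upward cause no occupation flow (the value equations carry
#' them). Value equations are the deterministic rate balance of every rule
#' evaluated with the limited coordinate replaced by its value, conditional
#' on the other dimensions' state.
#'
#' @param dims List of [dimension()] specs (declaration order fixes the
#'   equation ordering: states dimension-major with the first dimension
#'   varying fastest, explicit coordinates ascending, mean-field sentinel
#'   last; value equations after occupation equations; subsystems in
#'   declaration order).
#' @param rules List of [transition()] rules.
#' @param n_sub Number of replicated subsystems (sites). All share the same
#'   template; per-site heterogeneity enters through `site` covariates and
#'   the coupling.
#' @param couple Optional [coupling()] across subsystems.
#' @param site Optional list of per-site covariate vectors (each of length
#'   `n_sub`), passed to rate functions.
#' @param lazy If `TRUE`, only enumerate (counts and labels); do not compile
#'   the right-hand side. Used to count very large spatial systems without
#'   materialising their flow tables.
#' @return A `meanflame_system` object.
#' @export
build_system <- function(dims, rules, n_sub = 1L, couple = NULL, site = NULL,
                         lazy = FALSE) {
  if (inherits(dims, "meanflame_dimension")) dims <- list(dims)
  if (inherits(rules, "meanflame_transition")) rules <- list(rules)
  stopifnot(all(vapply(dims, inherits, TRUE, "meanflame_dimension")),
            all(vapply(rules, inherits, TRUE, "meanflame_transition")))
  dim_names <- vapply(dims, `[[`, "", "name")
  if (anyDuplicated(dim_names)) stop("duplicated dimension names")
  names(dims) <- dim_names
  for (r in rules) {
    bad <- setdiff(names(r$stoich), dim_names)
    if (length(bad)) {
      stop("transition '", r$name, "' references undeclared dimension(s): ",
           paste(bad, collapse = ", "))
    }
  }
  n_sub <- as.integer(n_sub)
  stopifnot(n_sub >= 1L)
  if (!is.null(couple)) {
    stopifnot(inherits(couple, "meanflame_coupling"))
    if (!couple$dimension %in% dim_names) {
      stop("coupling dimension '", couple$dimension, "' not declared")
    }
    if (nrow(couple$weights) != n_sub) {
      stop("coupling weight matrix must be ", n_sub, " x ", n_sub)
    }
  }
  if (!is.null(site)) {
    stopifnot(is.list(site),
              all(vapply(site, length, 0L) == n_sub))
  } else {
    site <- list()
  }

  pure <- vapply(dims, `[[`, TRUE, "pure_mf")
  exp_dims <- dims[!pure]
  pure_dims <- dims[pure]
  n_exp <- length(exp_dims)
  nc <- vapply(exp_dims, `[[`, 0L, "nc")
  mf <- vapply(exp_dims, `[[`, TRUE, "mf_limit")
  n_slots <- nc + as.integer(mf)          # explicit coords + MF sentinel

  # --- occupation state grid (template) ---------------------------------
  if (n_exp > 0L) {
    states <- as.matrix(expand.grid(lapply(n_slots, seq_len),
                                    KEEP.OUT.ATTRS = FALSE))
    colnames(states) <- names(exp_dims)
  } else {
    states <- matrix(integer(0), nrow = 1L, ncol = 0L)
  }
  n_states <- nrow(states)
  is_mf_slot <- function(s, k) mf[k] && s == n_slots[k]
  state_is_mf <- matrix(FALSE, n_states, max(n_exp, 1L))
  if (n_exp > 0L) {
    for (k in seq_len(n_exp)) state_is_mf[, k] <- mf[k] & states[, k] == n_slots[k]
  }
  keep_occ <- n_exp > 0L && any(nc >= 1L)
  n_occ <- if (keep_occ) n_states else 0L

  # --- value variables ---------------------------------------------------
  # exp dims with a limit: one value per combination of the other dims'
  # slots; pure dims: one value per occupation state.
  strides <- if (n_exp > 0L) cumprod(c(1L, n_slots[-n_exp])) else integer(0)
  state_id <- function(slots) 1L + sum((slots - 1L) * strides)

  val_dim <- character(0); val_cond <- list(); val_full_state <- list()
  val_offset <- integer(0)   # per dim block start (for lookup)
  val_block <- list()        # per dim: info for index computation
  for (d in dim_names) {
    if (dims[[d]]$pure_mf) {
      ids <- seq_len(n_states)
      val_offset[d] <- length(val_dim)
      val_block[[d]] <- list(kind = "pure")
      for (i in ids) {
        val_dim <- c(val_dim, d)
        val_cond[[length(val_cond) + 1L]] <- states[i, , drop = TRUE]
        val_full_state[[length(val_full_state) + 1L]] <- states[i, , drop = TRUE]
      }
    } else if (dims[[d]]$mf_limit) {
      k <- match(d, names(exp_dims))
      others <- setdiff(seq_len(n_exp), k)
      cond_grid <- if (length(others)) {
        as.matrix(expand.grid(lapply(n_slots[others], seq_len),
                              KEEP.OUT.ATTRS = FALSE))
      } else matrix(integer(0), nrow = 1L, ncol = 0L)
      val_offset[d] <- length(val_dim)
      ostr <- if (length(others)) cumprod(c(1L, n_slots[others][-length(others)])) else integer(0)
      val_block[[d]] <- list(kind = "exp", k = k, others = others, ostr = ostr)
      for (i in seq_len(nrow(cond_grid))) {
        sl <- rep(NA_integer_, n_exp)
        if (length(others)) sl[others] <- cond_grid[i, ]
        sl[k] <- n_slots[k]              # dimension itself at its MF sentinel
        names(sl) <- names(exp_dims)
        val_dim <- c(val_dim, d)
        cnd <- if (length(others)) cond_grid[i, , drop = TRUE] else integer(0)
        if (length(others)) names(cnd) <- names(exp_dims)[others]
        val_cond[[length(val_cond) + 1L]] <- cnd
        val_full_state[[length(val_full_state) + 1L]] <- sl
      }
    }
  }
  n_val <- length(val_dim)
  # value-var lookup from a full slot vector
  val_id <- function(d, slots) {
    bl <- val_block[[d]]
    if (is.null(bl)) stop("dimension '", d, "' carries no mean-field value")
    if (bl$kind == "pure") {
      val_offset[d] + state_id(slots)
    } else {
      o <- bl$others
      val_offset[d] +
        (if (length(o)) 1L + sum((slots[o] - 1L) * bl$ostr) else 1L)
    }
  }

  # --- labels ------------------------------------------------------------
  slot_label <- function(k, s) if (is_mf_slot(s, k)) "MF" else as.character(s - 1L)
  state_labels <- if (n_exp > 0L) {
    apply(states, 1L, function(sl) {
      paste0("P[", paste(vapply(seq_len(n_exp), function(k)
        slot_label(k, sl[k]), ""), collapse = ","), "]")
    })
  } else "P[]"
  val_labels <- vapply(seq_len(max(n_val, 0L)), function(v) {
    cnd <- val_cond[[v]]
    if (length(cnd)) {
      fs <- val_full_state[[v]]
      cl <- vapply(names(cnd), function(nm) {
        k <- match(nm, names(exp_dims))
        paste0(nm, "=", slot_label(k, cnd[[nm]]))
      }, "")
      paste0("V[", val_dim[v], "|", paste(cl, collapse = ","), "]")
    } else paste0("V[", val_dim[v], "]")
  }, "")
  tpl_labels <- c(if (keep_occ) state_labels else character(0), val_labels)
  n_per <- n_occ + n_val
  if (n_per == 0L) stop("system has no equations")
  n_eq <- n_per * n_sub
  labels <- if (n_sub == 1L) tpl_labels else
    as.vector(t(outer(seq_len(n_sub), tpl_labels,
                      function(s, l) paste0("s", s, ":", l))))

  # --- context rows (effective counts) -----------------------------------
  # For an occupation state or a value variable's implied full state, each
  # dimension contributes either a static coordinate or a dynamic reference
  # to a value variable.
  all_dim_names <- c(names(exp_dims), names(pure_dims))
  n_dims_all <- length(all_dim_names)
  context_row <- function(slots) {
    coord <- numeric(n_dims_all); vref <- rep(NA_integer_, n_dims_all)
    if (n_exp > 0L) for (k in seq_len(n_exp)) {
      if (is_mf_slot(slots[k], k)) vref[k] <- val_id(names(exp_dims)[k], slots)
      else coord[k] <- slots[k] - 1L
    }
    if (length(pure_dims)) for (p in seq_along(pure_dims)) {
      vref[n_exp + p] <- val_id(names(pure_dims)[p], slots)
    }
    list(coord = coord, vref = vref)
  }
  E_static <- matrix(0, n_states, n_dims_all,
                     dimnames = list(NULL, all_dim_names))
  E_vref <- matrix(NA_integer_, n_states, n_dims_all)
  for (i in seq_len(n_states)) {
    cr <- context_row(states[i, ])
    E_static[i, ] <- cr$coord; E_vref[i, ] <- cr$vref
  }
  CV_static <- matrix(0, max(n_val, 1L), n_dims_all,
                      dimnames = list(NULL, all_dim_names))
  CV_vref <- matrix(NA_integer_, max(n_val, 1L), n_dims_all)
  for (v in seq_len(n_val)) {
    cr <- context_row(val_full_state[[v]])
    CV_static[v, ] <- cr$coord; CV_vref[v, ] <- cr$vref
  }

  # --- occupation flow branches (template) -------------------------------
  branches <- list(); clips <- list()
  if (keep_occ) {
    for (ri in seq_along(rules)) {
      st <- rules[[ri]]$stoich
      dmove <- match(names(st), names(exp_dims))  # NA for pure dims
      exp_move <- which(!is.na(dmove))
      if (!length(exp_move)) next                 # value-only rule
      mdims <- dmove[exp_move]; mdelta <- as.integer(st[exp_move])
      acc <- list(plain = list(src = integer(0), tgt = integer(0)),
                  clip = list(src = integer(0)))
      acc_exit <- list(); acc_stay <- list()
      for (i in seq_len(n_states)) {
        sl <- states[i, ]
        mf_dec <- mdims[state_is_mf[i, mdims] & mdelta < 0]
        if (length(mf_dec) > 1L) {
          stop("transition '", rules[[ri]]$name,
               "' decrements two mean-field dimensions at once; unsupported")
        }
        move_target <- function(sl, skip = integer(0)) {
          # returns list(slots=..., ok=TRUE/clip/skip)
          out <- sl
          for (j in seq_along(mdims)) {
            k <- mdims[j]
            if (k %in% skip) next
            if (state_is_mf[i, k]) next  # stays inside its limit
            cc <- sl[k] - 1L + mdelta[j]
            if (cc < 0L) return(list(ok = "skip"))
            if (cc >= nc[k]) {
              if (mf[k]) out[k] <- n_slots[k]       # enters the limit
              else return(list(ok = "clip"))        # leaves hard truncation
            } else out[k] <- cc + 1L
          }
          list(ok = "ok", slots = out)
        }
        if (!length(mf_dec)) {
          expl_moving <- mdims[!state_is_mf[i, mdims]]
          if (!length(expl_moving)) next            # all movement inside limits
          tg <- move_target(sl)
          if (tg$ok == "skip") next
          if (tg$ok == "clip") {
            acc$clip$src <- c(acc$clip$src, i); next
          }
          j <- state_id(tg$slots)
          if (j == i) next
          acc$plain$src <- c(acc$plain$src, i)
          acc$plain$tgt <- c(acc$plain$tgt, j)
        } else {
          k <- mf_dec
          dk <- mdelta[match(k, mdims)]
          rv <- val_id(names(exp_dims)[k], sl)
          # exit branch: coordinate_k = nc_k, lands at nc_k + dk
          if (nc[k] + dk >= 0L && nc[k] >= 1L) {
            tg <- move_target(sl, skip = k)
            if (tg$ok == "clip") {
              acc$clip$src <- c(acc$clip$src, i)
            } else if (tg$ok == "ok") {
              out <- tg$slots; out[k] <- nc[k] + dk + 1L
              key <- as.character(k)
              if (is.null(acc_exit[[key]])) {
                acc_exit[[key]] <- list(src = integer(0), tgt = integer(0),
                                        rho_v = integer(0), k = k)
              }
              acc_exit[[key]]$src <- c(acc_exit[[key]]$src, i)
              acc_exit[[key]]$tgt <- c(acc_exit[[key]]$tgt, state_id(out))
              acc_exit[[key]]$rho_v <- c(acc_exit[[key]]$rho_v, rv)
            }
          }
          # stay branch: k keeps its limit, the other dimensions move
          tg <- move_target(sl, skip = k)
          if (tg$ok == "ok") {
            j <- state_id(tg$slots)
            if (j != i) {
              key <- as.character(k)
              if (is.null(acc_stay[[key]])) {
                acc_stay[[key]] <- list(src = integer(0), tgt = integer(0),
                                        rho_v = integer(0), k = k)
              }
              acc_stay[[key]]$src <- c(acc_stay[[key]]$src, i)
              acc_stay[[key]]$tgt <- c(acc_stay[[key]]$tgt, j)
              acc_stay[[key]]$rho_v <- c(acc_stay[[key]]$rho_v, rv)
            }
          } else if (tg$ok == "clip") {
            acc$clip$src <- c(acc$clip$src, i)
          }
        }
      }
      if (length(acc$plain$src)) {
        branches[[length(branches) + 1L]] <-
          list(rule = ri, type = "plain", src = acc$plain$src,
               tgt = acc$plain$tgt)
      }
      for (b in acc_exit) {
        branches[[length(branches) + 1L]] <-
          list(rule = ri, type = "exit", src = b$src, tgt = b$tgt,
               rho_v = b$rho_v, k = b$k, nc_k = nc[b$k])
      }
      for (b in acc_stay) {
        branches[[length(branches) + 1L]] <-
          list(rule = ri, type = "stay", src = b$src, tgt = b$tgt,
               rho_v = b$rho_v, k = b$k, nc_k = nc[b$k])
      }
      if (length(acc$clip$src)) {
        clips[[length(clips) + 1L]] <- list(rule = ri, src = acc$clip$src)
      }
    }
    # sources are unique within a group by construction, but two sources can
    # share a target (e.g. a diagonal event entering a limit from the edge
    # state and from inside the limit); split such groups into layers with
    # unique targets so that indexed accumulation in the RHS stays exact.
    split_unique <- function(b) {
      out <- list()
      remaining <- seq_along(b$src)
      while (length(remaining)) {
        first <- remaining[!duplicated(b$tgt[remaining])]
        piece <- b
        piece$src <- b$src[first]; piece$tgt <- b$tgt[first]
        if (!is.null(b$rho_v)) piece$rho_v <- b$rho_v[first]
        out[[length(out) + 1L]] <- piece
        remaining <- setdiff(remaining, first)
      }
      out
    }
    branches <- do.call(c, lapply(branches, split_unique))
  }

  # --- value blocks ------------------------------------------------------
  value_blocks <- list()
  if (n_val) {
    for (ri in seq_along(rules)) {
      st <- rules[[ri]]$stoich
      for (d in names(st)) {
        if (is.null(val_block[[d]])) next   # hard-truncated: no value eq
        rows <- which(val_dim == d)
        value_blocks[[length(value_blocks) + 1L]] <-
          list(rule = ri, rows = rows, d = as.numeric(st[[d]]))
      }
    }
  }

  sys <- structure(list(
    dims = dims, rules = rules, n_sub = n_sub, couple = couple, site = site,
    tpl = list(states = states, n_states = n_states, n_slots = n_slots,
               nc = nc, mf = mf, keep_occ = keep_occ, n_occ = n_occ,
               n_val = n_val, n_per = n_per, val_dim = val_dim,
               val_cond = val_cond, val_full_state = val_full_state,
               val_id = val_id, state_id = state_id,
               state_is_mf = state_is_mf,
               exp_names = names(exp_dims), pure_names = names(pure_dims),
               all_dim_names = all_dim_names,
               E_static = E_static, E_vref = E_vref,
               CV_static = CV_static, CV_vref = CV_vref,
               branches = branches, clips = clips,
               value_blocks = value_blocks,
               state_labels = state_labels, val_labels = val_labels),
    labels = labels, n_eq = n_eq, lazy = isTRUE(lazy)
  ), class = "meanflame_system")
  if (!lazy) sys <- compile_rhs(sys)
  sys
}

# Globalise template index arrays over subsystems and compile the RHS closure.
compile_rhs <- function(sys) {
  tpl <- sys$tpl; n_sub <- sys$n_sub
  n_per <- tpl$n_per; n_occ <- tpl$n_occ; n_val <- tpl$n_val
  n_states <- tpl$n_states
  off_eq <- (seq_len(n_sub) - 1L) * n_per
  off_E <- (seq_len(n_sub) - 1L) * n_states
  off_V <- off_eq + n_occ

  rep_idx <- function(idx, off) as.vector(outer(idx, off, `+`))

  # global effective-count matrix scaffolding
  E_static <- tpl$E_static[rep(seq_len(n_states), n_sub), , drop = FALSE]
  dyn <- which(!is.na(tpl$E_vref))
  if (length(dyn)) {
    rc <- arrayInd(dyn, dim(tpl$E_vref))
    E_dyn_pos <- as.vector(vapply(seq_len(n_sub), function(s)
      (rc[, 2L] - 1L) * (n_states * n_sub) + (rc[, 1L] + off_E[s]),
      numeric(nrow(rc))))
    E_dyn_y <- as.vector(vapply(seq_len(n_sub), function(s)
      tpl$E_vref[dyn] + off_V[s], numeric(length(dyn))))
  } else { E_dyn_pos <- integer(0); E_dyn_y <- integer(0) }

  CV_static <- tpl$CV_static[rep(seq_len(max(n_val, 1L)), n_sub), , drop = FALSE]
  cdyn <- which(!is.na(tpl$CV_vref))
  if (n_val && length(cdyn)) {
    rc <- arrayInd(cdyn, dim(tpl$CV_vref))
    CV_dyn_pos <- as.vector(vapply(seq_len(n_sub), function(s)
      (rc[, 2L] - 1L) * (max(n_val, 1L) * n_sub) +
        (rc[, 1L] + (s - 1L) * max(n_val, 1L)), numeric(nrow(rc))))
    CV_dyn_y <- as.vector(vapply(seq_len(n_sub), function(s)
      tpl$CV_vref[cdyn] + off_V[s], numeric(length(cdyn))))
  } else { CV_dyn_pos <- integer(0); CV_dyn_y <- integer(0) }

  site_expand <- function(site_id) lapply(sys$site, function(z) z[site_id])

  # occupation probability attached to each E row (virtual 1 when dropped)
  PofE <- if (tpl$keep_occ) rep_idx(seq_len(n_states), off_eq) else integer(0)

  gbranch <- list()
  for (b in tpl$branches) {
    len <- length(b$src)
    site_id <- rep(seq_len(n_sub), each = len)
    gb <- list(rule = b$rule, type = b$type,
               Erow = rep_idx(b$src, off_E),
               srcP = rep_idx(b$src, off_eq),
               tgtP = rep_idx(b$tgt, off_eq),
               site_id = site_id, site = site_expand(site_id))
    if (b$type != "plain") {
      gb$rho_y <- rep_idx(b$rho_v, off_V)
      gb$k_col <- b$k; gb$nc_k <- b$nc_k
    }
    gbranch[[length(gbranch) + 1L]] <- gb
  }
  gclip <- list()
  for (b in tpl$clips) {
    len <- length(b$src)
    site_id <- rep(seq_len(n_sub), each = len)
    gclip[[length(gclip) + 1L]] <-
      list(rule = b$rule, Erow = rep_idx(b$src, off_E),
           srcP = rep_idx(b$src, off_eq),
           site_id = site_id, site = site_expand(site_id))
  }
  gvalue <- list()
  for (vb in tpl$value_blocks) {
    len <- length(vb$rows)
    site_id <- rep(seq_len(n_sub), each = len)
    gvalue[[length(gvalue) + 1L]] <-
      list(rule = vb$rule, d = vb$d,
           CVrow = as.vector(outer(vb$rows, (seq_len(n_sub) - 1L) * max(n_val, 1L), `+`)),
           yidx = rep_idx(vb$rows, off_V),
           site_id = site_id, site = site_expand(site_id))
  }

  cpl <- sys$couple
  c_col <- if (!is.null(cpl)) match(cpl$dimension, tpl$all_dim_names) else NA_integer_
  rates <- lapply(sys$rules, `[[`, "rate")
  n_eq <- sys$n_eq
  keep_occ <- tpl$keep_occ

  theta_fn <- function(y, E) {
    if (is.null(cpl)) return(rep(0, n_sub))
    Pw <- if (keep_occ) y[PofE] else rep(1, nrow(E))
    ec <- E[, c_col] * Pw
    dim(ec) <- c(n_states, n_sub)
    as.vector(cpl$factor * (cpl$weights %*% colSums(ec)))
  }
  make_E <- function(y) {
    E <- E_static
    if (length(E_dyn_pos)) E[E_dyn_pos] <- y[E_dyn_y]
    E
  }
  rhs <- function(t, y, parms) {
    E <- make_E(y)
    theta <- theta_fn(y, E)
    dy <- numeric(n_eq)
    for (g in gbranch) {
      X <- E[g$Erow, , drop = FALSE]
      if (g$type == "exit") X[, g$k_col] <- g$nc_k
      r <- rates[[g$rule]](X, g$site, theta[g$site_id], t)
      if (g$type == "exit") {
        r <- r * rho(g$nc_k, pmax(y[g$rho_y], 0))
      } else if (g$type == "stay") {
        r <- r * (1 - rho(g$nc_k, pmax(y[g$rho_y], 0)))
      }
      r <- pmax(r, 0)
      flow <- r * y[g$srcP]
      dy[g$srcP] <- dy[g$srcP] - flow
      dy[g$tgtP] <- dy[g$tgtP] + flow
    }
    if (length(gvalue)) {
      CV <- CV_static
      if (length(CV_dyn_pos)) CV[CV_dyn_pos] <- y[CV_dyn_y]
      for (g in gvalue) {
        X <- CV[g$CVrow, , drop = FALSE]
        r <- rates[[g$rule]](X, g$site, theta[g$site_id], t)
        dy[g$yidx] <- dy[g$yidx] + g$d * r
      }
    }
    list(dy)
  }
  sys$rhs <- rhs
  sys$internals <- list(make_E = make_E, theta_fn = theta_fn, PofE = PofE,
                        gclip = gclip, gvalue = gvalue, gbranch = gbranch,
                        off_eq = off_eq, off_V = off_V, off_E = off_E)
  sys
}

#' Number of scalar ODEs in a built system
#' @param system A `meanflame_system`, `meanflame_exact` or any other build
#'   exposing an equation count (e.g. the classic mean-field comparators).
#' @return Positive integer.
#' @export
count_equations <- function(system) {
  if (is.null(system$n_eq)) stop("not a built equation system")
  system$n_eq
}

#' Occupation-state bookkeeping
#'
#' Counts the explicit master-equation states, the mean-field-limit
#' occupation states and the mean-field value equations per subsystem.
#' @param system A `meanflame_system`.
#' @return List with `explicit`, `mf_limit`, `values`, `per_subsystem`,
#'   `total`.
#' @export
state_counts <- function(system) {
  tpl <- system$tpl
  n_mf <- if (tpl$keep_occ) sum(apply(
    tpl$state_is_mf[, seq_along(tpl$exp_names), drop = FALSE], 1L, any)) else 0L
  list(explicit = if (tpl$keep_occ) tpl$n_states - n_mf else 0L,
       mf_limit = n_mf, values = tpl$n_val,
       per_subsystem = tpl$n_per, total = system$n_eq)
}

#' Equation enumeration table
#'
#' One row per scalar equation: subsystem, kind (occupation or mf_value),
#' template index and label. Writable as CSV for serialisation round-trips.
#' @param system A non-lazy `meanflame_system`.
#' @param file Optional path; if given the table is written as CSV.
#' @return A data.frame (invisibly when `file` is given).
#' @export
equation_table <- function(system, file = NULL) {
  tpl <- system$tpl
  kind <- c(rep("occupation", tpl$n_occ), rep("mf_value", tpl$n_val))
  df <- data.frame(
    subsystem = rep(seq_len(system$n_sub), each = tpl$n_per),
    kind = rep(kind, system$n_sub),
    index = rep(seq_len(tpl$n_per), system$n_sub),
    label = system$labels,
    stringsAsFactors = FALSE
  )
  if (!is.null(file)) {
    utils::write.csv(df, file, row.names = FALSE)
    return(invisible(df))
  }
  df
}

#' @export
print.meanflame_system <- function(x, ...) {
  sc <- state_counts(x)
  cat("mean-FLAME system:", x$n_eq, "equations\n")
  cat("  subsystems:", x$n_sub, " (", sc$per_subsystem, "equations each )\n")
  cat("  per subsystem:", sc$explicit, "explicit +", sc$mf_limit,
      "mean-field-limit occupation states,", sc$values, "value equations\n")
  cat("  dimensions:", paste(vapply(x$dims, function(d) {
    paste0(d$name, if (d$pure_mf) " (pure MF)"
           else paste0(" (nc=", d$nc, if (!d$mf_limit) ", truncated" else "", ")"))
  }, ""), collapse = ", "), "\n")
  if (!is.null(x$couple)) cat("  coupled through dimension:", x$couple$dimension, "\n")
  invisible(x)
}
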