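#' Build an initial state vector
#'
#' Places a point mass of occupation probability on the state corresponding
#' to the given starting counts in every subsystem, and initialises the
#' mean-field values. A count at or above a dimension's cutoff starts the
#' subsystem inside that dimension's mean-field limit.
#'
#' Mean-field values default to the cutoff `nc` of their dimension -- the
#' entry point of any trajectory into the limit -- except for classic
#' mean-field dimensions (`nc = 0`), whose value starts at the given count.
#' Pure mean-field dimensions default to 0. Both can be overridden through
#' `values`.
#'
#' @param system A `meanflame_system`.
#' @param counts Named numeric vector of starting counts per non-pure
#'   dimension (recycled over subsystems), or a matrix with one row per
#'   subsystem and named columns.
#' @param values Named list of overrides for mean-field values (scalar or
#'   per-subsystem vector per dimension name), including pure dimensions
#'   (e.g. `list(s = 10, g = 20)`).
#' @param occupation Optional list (per subsystem) of `list(state =, prob =)`
#'   entries giving a sparse occupation map instead of a point mass;
#'   `state` is a named count vector, with `NA` marking a mean-field slot.
#' @return Named numeric vector of length `count_equations(system)`.
#' @export
initial_condition <- function(system, counts = NULL, values = list(),
                              occupation = NULL) {
  stopifnot(inherits(system, "meanflame_system"))
  tpl <- system$tpl
  n_sub <- system$n_sub
  exp_names <- tpl$exp_names
  y <- numeric(system$n_eq)
  names(y) <- system$labels
  off_eq <- (seq_len(n_sub) - 1L) * tpl$n_per

  cnt <- matrix(0, n_sub, length(exp_names), dimnames = list(NULL, exp_names))
  if (!is.null(counts)) {
    if (is.matrix(counts)) {
      cnt[, colnames(counts)] <- counts
    } else {
      for (nm in names(counts)) cnt[, nm] <- counts[[nm]]
    }
  }
  count_to_slot <- function(k, n) {
    n <- as.integer(n)
    if (tpl$mf[k]) {
      if (n >= tpl$nc[k]) tpl$n_slots[k] else n + 1L
    } else {
      if (n >= tpl$nc[k]) stop("count ", n, " outside hard truncation of '",
                               exp_names[k], "'")
      n + 1L
    }
  }
  if (tpl$keep_occ) {
    for (s in seq_len(n_sub)) {
      if (!is.null(occupation)) {
        for (entry in occupation[[s]]) {
          slots <- vapply(seq_along(exp_names), function(k) {
            v <- entry$state[[exp_names[k]]]
            if (is.na(v)) tpl$n_slots[k] else count_to_slot(k, v)
          }, 0L)
          y[off_eq[s] + tpl$state_id(slots)] <-
            y[off_eq[s] + tpl$state_id(slots)] + entry$prob
        }
      } else {
        slots <- vapply(seq_along(exp_names), function(k)
          count_to_slot(k, cnt[s, k]), 0L)
        y[off_eq[s] + tpl$state_id(slots)] <- 1
      }
    }
  }
  # mean-field values
  for (v in seq_len(tpl$n_val)) {
    d <- tpl$val_dim[v]
    for (s in seq_len(n_sub)) {
      pos <- off_eq[s] + tpl$n_occ + v
      if (!is.null(values[[d]])) {
        vv <- values[[d]]
        y[pos] <- if (length(vv) == 1L) vv else vv[s]
      } else if (system$dims[[d]]$pure_mf) {
        y[pos] <- 0
      } else {
        k <- match(d, exp_names)
        y[pos] <- if (tpl$nc[k] == 0L) cnt[s, k] else tpl$nc[k]
      }
    }
  }
  y
}

#' Expected count of a dimension
#'
#' Weighted average of the dimension's count over the occupation
#' distribution: explicit states contribute their integer coordinate,
#' mean-field-limit states contribute their current mean-field value.
#'
#' @param system A non-lazy `meanflame_system`.
#' @param y State vector (as produced by [initial_condition()] or a solution
#'   row).
#' @param dimension Dimension name.
#' @return Numeric vector of expected counts, one per subsystem.
#' @export
expected_count <- function(system, y, dimension) {
  stopifnot(inherits(system, "meanflame_system"), !system$lazy)
  tpl <- system$tpl
  col <- match(dimension, tpl$all_dim_names)
  if (is.na(col)) stop("unknown dimension '", dimension, "'")
  E <- system$internals$make_E(y)
  Pw <- if (tpl$keep_occ) y[system$internals$PofE] else rep(1, nrow(E))
  ec <- E[, col] * Pw
  dim(ec) <- c(tpl$n_states, system$n_sub)
  colSums(ec)
}

#' Expected influx coupling from neighbour subsystems
#'
#' The mean-field coupling: `factor` times the summed expected count of
#' `dimension` over the given neighbour states.
#'
#' @param neighbors List of neighbour states, each a `list(system =, y =)`
#'   pair (or a single such pair).
#' @param dimension Dimension whose expected count is exported.
#' @param factor Nonnegative coupling factor (a migration rate, or
#'   lambda * beta for contact coupling).
#' @return Single nonnegative rate.
#' @export
coupling_theta <- function(neighbors, dimension, factor) {
  if (length(factor) != 1L || is.na(factor) || factor < 0) {
    stop("`factor` must be a single nonnegative value")
  }
  if (length(neighbors) && !is.null(neighbors$system)) neighbors <- list(neighbors)
  if (!length(neighbors)) return(0)
  factor * sum(vapply(neighbors, function(nb)
    sum(expected_count(nb$system, nb$y, dimension)), 0))
}

#' Occupation probabilities of one subsystem
#'
#' @param system A `meanflame_system`.
#' @param y State vector.
#' @param subsystem Subsystem index.
#' @return Named numeric vector over the subsystem's occupation states
#'   (length zero when the build has no explicit states).
#' @export
occupation_probabilities <- function(system, y, subsystem = 1L) {
  tpl <- system$tpl
  if (!tpl$keep_occ) return(numeric(0))
  idx <- (subsystem - 1L) * tpl$n_per + seq_len(tpl$n_occ)
  stats::setNames(y[idx], tpl$state_labels)
}

#' Mean-field values of one subsystem
#' @inheritParams occupation_probabilities
#' @return Named numeric vector over the subsystem's value equations.
#' @export
mf_values <- function(system, y, subsystem = 1L) {
  tpl <- system$tpl
  idx <- (subsystem - 1L) * tpl$n_per + tpl$n_occ + seq_len(tpl$n_val)
  stats::setNames(y[idx], tpl$val_labels)
}

#' Marginal count distribution of one dimension
#'
#' Expands the occupation distribution of a subsystem over integer counts of
#' one dimension: explicit states contribute point masses at their
#' coordinate, mean-field-limit states are expanded with the
#' truncated-Poisson shape implied by their current value.
#'
#' @inheritParams occupation_probabilities
#' @param dimension Dimension name (non-pure).
#' @param max_count Upper end of the returned support (counts
#'   `0..max_count`).
#' @return Numeric vector of probabilities of length `max_count + 1`.
#' @export
marginal_distribution <- function(system, y, dimension, max_count,
                                  subsystem = 1L) {
  tpl <- system$tpl
  k <- match(dimension, tpl$exp_names)
  if (is.na(k)) stop("unknown explicit dimension '", dimension, "'")
  out <- numeric(max_count + 1L)
  off <- (subsystem - 1L) * tpl$n_per
  if (!tpl$keep_occ) stop("build has no occupation states")
  for (i in seq_len(tpl$n_states)) {
    p <- y[off + i]
    if (p <= 0) next
    if (tpl$state_is_mf[i, k]) {
      v <- max(y[off + tpl$n_occ + tpl$val_id(dimension, tpl$states[i, ])], 0)
      out <- out + p * truncated_poisson_pmf(0:max_count, tpl$nc[k], v)
    } else {
      cc <- tpl$states[i, k] - 1L
      if (cc <= max_count) out[cc + 1L] <- out[cc + 1L] + p
    }
  }
  out
}
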