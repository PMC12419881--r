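#' Exact master equation on a truncated lattice
#'
#' Independent reference build: enumerates the full truncated state space
#' (counts `0..trunc-1` per dimension) and assembles the sparse generator
#' matrix Q directly from the transition rules, so that `dP/dt = Q P`.
#' Events that would leave the truncation are dropped (rate treated as zero
#' at the boundary). Rates are evaluated at `t = 0` with zero coupling;
#' time-dependent rates are not supported here.
#'
#' @param truncations Named integer vector: number of explicit states per
#'   dimension.
#' @param rules List of [transition()] rules over those dimensions.
#' @param site Optional list of scalar covariates passed to the rate
#'   functions (e.g. `list(N = 50)`).
#' @return A `meanflame_exact` object with the sparse generator `Q`, the
#'   state coordinate matrix, labels, an `rhs` closure and `n_eq`.
#' @export
full_master_equation <- function(truncations, rules, site = list()) {
  if (inherits(rules, "meanflame_transition")) rules <- list(rules)
  stopifnot(!is.null(names(truncations)), all(truncations >= 1))
  dn <- names(truncations)
  states <- as.matrix(expand.grid(lapply(truncations, function(m) 0:(m - 1L)),
                                  KEEP.OUT.ATTRS = FALSE))
  colnames(states) <- dn
  n <- nrow(states)
  strides <- cumprod(c(1L, truncations[-length(truncations)]))
  sid <- function(coords) 1L + as.integer(coords %*% strides)
  site_rows <- lapply(site, function(z) rep(z, length.out = n))
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  dropped <- 0L
  for (r in rules) {
    d <- match(names(r$stoich), dn)
    if (anyNA(d)) stop("rule '", r$name, "' references unknown dimension")
    rate <- pmax(r$rate(states, site_rows, rep(0, n), 0), 0)
    tgt <- states
    for (j in seq_along(d)) tgt[, d[j]] <- tgt[, d[j]] + r$stoich[j]
    ok <- rep(TRUE, n)
    for (j in seq_along(d)) {
      ok <- ok & tgt[, d[j]] >= 0L & tgt[, d[j]] <= truncations[d[j]] - 1L
    }
    dropped <- dropped + sum(!ok & rate > 0)
    src <- which(ok & rate > 0)
    if (!length(src)) next
    tid <- sid(tgt[src, , drop = FALSE])
    ii <- c(ii, tid, src); jj <- c(jj, src, src)
    xx <- c(xx, rate[src], -rate[src])
  }
  Q <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n))
  labels <- apply(states, 1L, function(cc)
    paste0("P[", paste(cc, collapse = ","), "]"))
  rhs <- function(t, y, parms) list(as.vector(Q %*% y))
  structure(list(Q = Q, states = states, labels = labels, n_eq = n,
                 rhs = rhs, truncations = truncations,
                 n_dropped_events = dropped),
            class = "meanflame_exact")
}

#' @export
print.meanflame_exact <- function(x, ...) {
  cat("exact master equation:", x$n_eq, "states (",
      paste(x$truncations, collapse = " x "), ")\n")
  invisible(x)
}

#' Sparse generator matrix of a built system
#'
#' For hard-truncated (no mean-field limit, no values) single-subsystem
#' builds of [build_system()], assembles the generator Q with
#' `dP/dt = Q P` from the compiled flow branches (rates evaluated at
#' `t = 0`, zero coupling). Columns sum to zero.
#'
#' @param system A non-lazy `meanflame_system` without value equations, or a
#'   `meanflame_exact` build (whose Q is returned directly).
#' @return A sparse `dgCMatrix`.
#' @export
generator_matrix <- function(system) {
  if (inherits(system, "meanflame_exact")) return(system$Q)
  stopifnot(inherits(system, "meanflame_system"), !system$lazy)
  if (system$tpl$n_val > 0L) {
    stop("generator matrix is only defined for purely explicit ",
         "(hard-truncated) builds")
  }
  n <- system$n_eq
  y <- numeric(n)
  E <- system$internals$make_E(y)
  theta <- rep(0, system$n_sub)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (g in system$internals$gbranch) {
    X <- E[g$Erow, , drop = FALSE]
    r <- pmax(system$rules[[g$rule]]$rate(X, g$site, theta[g$site_id], 0), 0)
    ii <- c(ii, g$tgtP, g$srcP); jj <- c(jj, g$srcP, g$srcP)
    xx <- c(xx, r, -r)
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n))
}

#' Gillespie stochastic simulation
#'
#' Statistically exact event-by-event simulation of the continuous-time
#' Markov jump process defined by an event stoichiometry matrix and a rate
#' function.
#'
#' @param stoich Integer matrix, one row per event type, one named column
#'   per state coordinate.
#' @param rates_fn Function `(state, t)` returning the vector of event
#'   rates.
#' @param state0 Named integer initial state.
#' @param t_end End time.
#' @param seed Optional integer; when given, `set.seed(seed)` is called and
#'   the seed is recorded on the result.
#' @param record If `TRUE`, the full event path is returned; otherwise only
#'   the final state (faster for ensemble runs).
#' @param max_events Stop after this many events (e.g. 1 to sample the first
#'   jump of the embedded chain).
#' @return If `record`, a `meanflame_trajectory`: list with `times` (event
#'   times, starting at 0), `states` (matrix, one row per event time) and
#'   `seed`. Otherwise the final state vector at `t_end`.
#' @export
gillespie <- function(stoich, rates_fn, state0, t_end, seed = NULL,
                      record = TRUE, max_events = Inf) {
  if (!is.null(seed)) set.seed(seed)
  stoich <- as.matrix(stoich)
  state <- as.numeric(state0)
  nm <- names(state0)
  t <- 0
  n_events <- 0L
  if (record) {
    cap <- 256L
    times <- numeric(cap); path <- matrix(0, cap, length(state))
    times[1L] <- 0; path[1L, ] <- state; np <- 1L
  }
  repeat {
    if (n_events >= max_events) break
    rts <- pmax(rates_fn(state, t), 0)
    tot <- sum(rts)
    if (!is.finite(tot)) stop("infinite total rate")
    if (tot <= 0) break
    t <- t + stats::rexp(1L, tot)
    if (t > t_end) break
    ev <- sample.int(length(rts), 1L, prob = rts)
    state <- state + stoich[ev, ]
    n_events <- n_events + 1L
    if (record) {
      np <- np + 1L
      if (np > cap) {
        cap <- cap * 2L
        times <- c(times, numeric(cap / 2L))
        path <- rbind(path, matrix(0, cap / 2L, length(state)))
      }
      times[np] <- t; path[np, ] <- state
    }
  }
  if (!record) return(stats::setNames(state, nm))
  colnames(path) <- nm
  structure(list(times = times[seq_len(np)],
                 states = path[seq_len(np), , drop = FALSE], seed = seed),
            class = "meanflame_trajectory")
}

#' Event stoichiometry and rates from transition rules
#'
#' Adapts a list of [transition()] rules on integer states to the
#' `(stoich, rates_fn)` interface of [gillespie()].
#'
#' @param rules List of [transition()] rules.
#' @param dim_names Coordinate names of the simulated state.
#' @param site Optional list of scalar covariates.
#' @param theta Constant coupling value (default 0).
#' @return List with `stoich` and `rates_fn`.
#' @export
ssa_events <- function(rules, dim_names, site = list(), theta = 0) {
  if (inherits(rules, "meanflame_transition")) rules <- list(rules)
  stoich <- matrix(0L, length(rules), length(dim_names),
                   dimnames = list(NULL, dim_names))
  for (i in seq_along(rules)) {
    stoich[i, names(rules[[i]]$stoich)] <- rules[[i]]$stoich
  }
  rates_fn <- function(state, t) {
    x <- matrix(state, 1L, dimnames = list(NULL, dim_names))
    vapply(rules, function(r) r$rate(x, site, theta, t)[1L], 0)
  }
  list(stoich = stoich, rates_fn = rates_fn)
}

#' Absorption before exceeding the starting count
#'
#' Probability that the embedded jump chain of a one-dimensional process
#' reaches the absorbing state before ever exceeding its starting count,
#' computed by a linear solve on the jump-chain hitting equations. With
#' `start = 1` this is the classic first-step probability that a single
#' individual dies before reproducing, `nu/(mu + nu)` for a birth-death
#' process with birth rate `mu*n` and death rate `nu*n^2`.
#'
#' @param rules List of [transition()] rules over one dimension.
#' @param start Starting count.
#' @param absorbing Absorbing count (default 0).
#' @param dim_name Name of the dimension (default taken from the rules).
#' @return Probability in `[0, 1]`; 1 when already absorbed, 0 when the
#'   absorbing state is unreachable.
#' @export
first_passage_absorption <- function(rules, start, absorbing = 0L,
                                     dim_name = NULL) {
  if (inherits(rules, "meanflame_transition")) rules <- list(rules)
  if (is.null(dim_name)) dim_name <- names(rules[[1L]]$stoich)[1L]
  if (start <= absorbing) return(1)
  states <- absorbing:start          # barrier: anything above `start` fails
  n <- length(states)
  rate_at <- function(cnt) {
    x <- matrix(cnt, 1L, dimnames = list(NULL, dim_name))
    vapply(rules, function(r) max(r$rate(x, list(), 0, 0)[1L], 0), 0)
  }
  # transition probabilities of the embedded jump chain
  A <- diag(n); b <- numeric(n)
  A[1L, ] <- 0; A[1L, 1L] <- 1; b[1L] <- 1   # absorbing state hit
  for (i in 2:n) {
    cnt <- states[i]
    rts <- rate_at(cnt)
    tot <- sum(rts)
    if (tot <= 0) { b[i] <- 0; next }        # stuck: never absorbed
    for (j in seq_along(rules)) {
      tgt <- cnt + rules[[j]]$stoich[[dim_name]]
      p <- rts[j] / tot
      if (p == 0) next
      if (tgt > start) next                  # exceeds the barrier: lost
      k <- match(tgt, states)
      A[i, k] <- A[i, k] - p
    }
  }
  h <- tryCatch(solve(A, b), error = function(e) NULL)
  if (is.null(h)) return(0)
  max(min(h[n], 1), 0)
}
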