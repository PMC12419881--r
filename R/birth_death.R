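#' Birth-death model parameters
#'
#' A single population where births occur at rate `mu * n` and deaths at
#' rate `nu * n^2`. Extinction (`n = 0`) is absorbing; the metastable state
#' sits at `n = mu/nu`. In the coupled variant, births in one subsystem also
#' arrive from the partner at the migration rate `lam` per expected
#' individual there.
#'
#' @param mu Per-capita birth rate.
#' @param nu Pairwise death coefficient (death rate `nu * n^2`).
#' @param lam Migration factor (coupled variant only).
#' @param nc Cutoff: number of explicit master-equation states; counts
#'   `>= nc` form the mean-field limit. `nc = 0` is the classic mean-field
#'   model.
#' @return A parameter list of class `bd_params`.
#' @export
bd_params <- function(mu, nu, lam = 0, nc = 8L) {
  stopifnot(mu >= 0, nu >= 0, lam >= 0, nc >= 0)
  structure(list(mu = mu, nu = nu, lam = lam, nc = as.integer(nc)),
            class = "bd_params")
}

bd_rules <- function(mu, nu) {
  list(
    transition(c(n = 1), function(x, site, theta, t)
      mu * x[, "n"] + theta, "birth"),
    transition(c(n = -1), function(x, site, theta, t)
      nu * x[, "n"]^2, "death")
  )
}

#' Single birth-death system with a mean-field limit
#'
#' `nc` explicit occupation states, one mean-field-limit occupation state
#' and one value equation (which is exactly the classic mean-field ODE
#' `dI/dt = mu*I - nu*I^2`). With `nc = 0` the build collapses to that
#' single mean-field equation.
#'
#' @param params A [bd_params()].
#' @return A `meanflame_system`.
#' @export
build_birth_death <- function(params) {
  stopifnot(inherits(params, "bd_params"))
  build_system(dimension("n", params$nc),
               bd_rules(params$mu, params$nu))
}

#' Two coupled birth-death subsystems
#'
#' Each subsystem carries its own hybrid build; they are joined through the
#' expected-influx coupling `theta_i = lam * E[n_j]`, recomputed from the
#' partner's current state at every right-hand-side evaluation. Note that
#' the local extinction state is no longer absorbing under this average
#' coupling.
#'
#' @param params A [bd_params()] with `lam` set.
#' @return A `meanflame_system` with two subsystems.
#' @export
build_birth_death_pair <- function(params) {
  stopifnot(inherits(params, "bd_params"))
  build_system(dimension("n", params$nc),
               bd_rules(params$mu, params$nu),
               n_sub = 2L,
               couple = coupling("n", params$lam,
                                 matrix(c(0, 1, 1, 0), 2L)))
}

#' Exact truncated master equation for the single birth-death process
#'
#' @param params A [bd_params()].
#' @param n_states Truncation: counts `0..n_states-1` are tracked.
#' @return A `meanflame_exact` build.
#' @export
build_birth_death_exact <- function(params, n_states = 100L) {
  full_master_equation(c(n = as.integer(n_states)),
                       bd_rules(params$mu, params$nu))
}

#' Exact joint master equation for the coupled pair
#'
#' Joint two-dimensional build over both subsystems' counts with the exact
#' cross birth term `mu*n_i + lam*n_j` -- the oracle that retains all
#' inter-subsystem correlations.
#'
#' @param params A [bd_params()] with `lam` set.
#' @param n_states Truncation per subsystem.
#' @return A `meanflame_exact` build with `n_states^2` equations.
#' @export
build_birth_death_pair_exact <- function(params, n_states = 50L) {
  mu <- params$mu; nu <- params$nu; lam <- params$lam
  rules <- list(
    transition(c(n1 = 1), function(x, site, theta, t)
      mu * x[, "n1"] + lam * x[, "n2"], "birth1"),
    transition(c(n1 = -1), function(x, site, theta, t)
      nu * x[, "n1"]^2, "death1"),
    transition(c(n2 = 1), function(x, site, theta, t)
      mu * x[, "n2"] + lam * x[, "n1"], "birth2"),
    transition(c(n2 = -1), function(x, site, theta, t)
      nu * x[, "n2"]^2, "death2")
  )
  full_master_equation(c(n1 = as.integer(n_states),
                         n2 = as.integer(n_states)), rules)
}
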