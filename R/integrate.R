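#' Integration settings
#'
#' @param times Output time grid (first entry is the initial time).
#' @param method A `deSolve` method name. `"lsoda"` (stiff-capable, default)
#'   suits the small and medium builds; `"rk4"` with a fixed internal step
#'   (`hini`) is useful for large spatial builds where forming a dense
#'   Jacobian is too expensive.
#' @param rtol,atol Relative and absolute tolerances.
#' @param hini Initial/fixed internal step (used by fixed-step methods).
#' @param maxsteps Maximal number of internal steps per output interval.
#' @return An `integration_config` object.
#' @export
integration_config <- function(times, method = "lsoda", rtol = 1e-8,
                               atol = 1e-10, hini = 0, maxsteps = 20000L) {
  stopifnot(is.numeric(times), length(times) >= 2L, rtol > 0, atol > 0)
  structure(list(times = times, method = method, rtol = rtol, atol = atol,
                 hini = hini, maxsteps = maxsteps),
            class = "integration_config")
}

#' Integrate an assembled system
#'
#' Runs the system's right-hand side over the configured time grid and
#' attaches conservation diagnostics: the maximal deviation of the total
#' occupation probability from 1 in any subsystem, and a flag for occupation
#' entries dipping below `-10 * atol`. Occupation entries are never clipped
#' during integration; they are only flagged, since clipping silently
#' destroys probability conservation.
#'
#' @param system A non-lazy `meanflame_system` (or any object with `$rhs`
#'   and `$n_eq`, such as the exact-reference builds).
#' @param y0 Initial state from [initial_condition()].
#' @param config An [integration_config()].
#' @return A `meanflame_solution`: list with `times`, `y` (matrix, one row
#'   per time), `system`, `diagnostics`.
#' @export
integrate_system <- function(system, y0, config) {
  stopifnot(inherits(config, "integration_config"))
  if (isTRUE(system$lazy)) stop("cannot integrate a lazily built system")
  stopifnot(length(y0) == system$n_eq)
  out <- deSolve::ode(y = unname(y0), times = config$times,
                      func = system$rhs, parms = NULL,
                      method = config$method, rtol = config$rtol,
                      atol = config$atol, hini = config$hini,
                      maxsteps = config$maxsteps)
  if (attr(out, "istate")[1L] < 0) stop("integrator failed")
  y <- unname(out[, -1L, drop = FALSE])
  sol <- structure(list(times = out[, 1L], y = y, system = system),
                   class = "meanflame_solution")
  sol$diagnostics <- conservation_report(sol)
  if (sol$diagnostics$negative_breach) {
    warning("occupation entries below -10*atol (min ",
            format(sol$diagnostics$min_occupation), ")")
  }
  sol
}

#' Conservation diagnostics of a solution
#'
#' @param sol A `meanflame_solution`.
#' @return List: `max_conservation_error` (max over times and subsystems of
#'   |sum of occupation - 1|), `min_occupation`, `negative_breach`.
#' @export
conservation_report <- function(sol) {
  sys <- sol$system
  if (!inherits(sys, "meanflame_system") || !sys$tpl$keep_occ) {
    return(list(max_conservation_error = 0, min_occupation = 0,
                negative_breach = FALSE))
  }
  tpl <- sys$tpl
  err <- 0; mn <- Inf
  for (s in seq_len(sys$n_sub)) {
    idx <- (s - 1L) * tpl$n_per + seq_len(tpl$n_occ)
    tot <- rowSums(sol$y[, idx, drop = FALSE])
    err <- max(err, max(abs(tot - 1)))
    mn <- min(mn, min(sol$y[, idx]))
  }
  atol <- 1e-10
  list(max_conservation_error = err, min_occupation = mn,
       negative_breach = mn < -10 * atol)
}

#' State vector at a given time
#'
#' @param sol A `meanflame_solution`.
#' @param t Requested time; must lie on the solution grid (within rounding).
#' @return Named numeric state vector.
#' @export
solution_state <- function(sol, t) {
  i <- which.min(abs(sol$times - t))
  if (abs(sol$times[i] - t) > 1e-8 * max(1, abs(t))) {
    stop("time ", t, " is not on the solution grid")
  }
  stats::setNames(sol$y[i, ], sol$system$labels)
}

#' Staged integration: values first, occupations second
#'
#' The mean-field value equations of a closed (uncoupled) build evolve
#' autonomously: they never depend on the occupation probabilities. They can
#' therefore be integrated first and fed into the occupation equations as a
#' known time course, which sidesteps scale mismatches between tiny
#' occupation probabilities and large mean-field values in a single system.
#' Refuses systems with a cross-subsystem coupling, whose values depend on
#' occupations through theta.
#'
#' @inheritParams integrate_system
#' @param refine Factor by which the value-stage grid is refined relative to
#'   the output grid (linear interpolation feeds stage two).
#' @return A `meanflame_solution` (same layout as [integrate_system()]).
#' @export
integrate_staged <- function(system, y0, config, refine = 4L) {
  stopifnot(inherits(system, "meanflame_system"), !system$lazy)
  if (!is.null(system$couple)) {
    stop("staged integration requires autonomous mean-field values; ",
         "this system is coupled through theta")
  }
  tpl <- system$tpl
  if (tpl$n_val == 0L) return(integrate_system(system, y0, config))
  n_sub <- system$n_sub
  off_V <- (seq_len(n_sub) - 1L) * tpl$n_per + tpl$n_occ
  vpos <- as.vector(outer(seq_len(tpl$n_val), off_V, `+`))
  occ_pos <- if (tpl$keep_occ) {
    as.vector(outer(seq_len(tpl$n_occ), (seq_len(n_sub) - 1L) * tpl$n_per, `+`))
  } else integer(0)
  n_eq <- system$n_eq
  rhs_full <- system$rhs

  # stage 1: values only (their RHS reads only value entries of y)
  rhs_v <- function(t, V, parms) {
    y <- numeric(n_eq); y[vpos] <- V
    list(rhs_full(t, y, parms)[[1L]][vpos])
  }
  tfine <- sort(unique(c(config$times,
                         seq(min(config$times), max(config$times),
                             length.out = refine * length(config$times)))))
  sv <- deSolve::ode(y = unname(y0[vpos]), times = tfine, func = rhs_v,
                     parms = NULL, method = config$method,
                     rtol = config$rtol, atol = config$atol)
  if (attr(sv, "istate")[1L] < 0) stop("value-stage integration failed")
  Vt <- sv[, -1L, drop = FALSE]
  interp <- lapply(seq_along(vpos), function(j)
    stats::approxfun(tfine, Vt[, j], rule = 2))

  if (!tpl$keep_occ) {
    keep <- match(config$times, tfine)
    y <- matrix(0, length(config$times), n_eq)
    y[, vpos] <- Vt[keep, , drop = FALSE]
    sol <- structure(list(times = config$times, y = y, system = system),
                     class = "meanflame_solution")
    sol$diagnostics <- conservation_report(sol)
    return(sol)
  }
  # stage 2: occupations with the value time course held fixed
  rhs_p <- function(t, P, parms) {
    y <- numeric(n_eq)
    y[vpos] <- vapply(interp, function(f) f(t), 0)
    y[occ_pos] <- P
    list(rhs_full(t, y, parms)[[1L]][occ_pos])
  }
  sp <- deSolve::ode(y = unname(y0[occ_pos]), times = config$times,
                     func = rhs_p, parms = NULL, method = config$method,
                     rtol = config$rtol, atol = config$atol)
  if (attr(sp, "istate")[1L] < 0) stop("occupation-stage integration failed")
  keep <- match(config$times, tfine)
  y <- matrix(0, length(config$times), n_eq)
  y[, vpos] <- Vt[keep, , drop = FALSE]
  y[, occ_pos] <- sp[, -1L, drop = FALSE]
  sol <- structure(list(times = config$times, y = y, system = system),
                   class = "meanflame_solution")
  sol$diagnostics <- conservation_report(sol)
  sol
}

#' Probability flux lost at a hard truncation boundary
#'
#' For builds with hard-truncated dimensions, events that would leave the
#' truncation are dropped (their rate is treated as zero). This reports the
#' instantaneous rate at which probability would have left through those
#' dropped events, a diagnostic for whether the truncation was wide enough.
#'
#' @param system A non-lazy `meanflame_system`.
#' @param y State vector.
#' @param t Time (for time-dependent rates).
#' @return Single nonnegative rate.
#' @export
lost_flux <- function(system, y, t = 0) {
  stopifnot(inherits(system, "meanflame_system"), !system$lazy)
  gclip <- system$internals$gclip
  if (!length(gclip)) return(0)
  E <- system$internals$make_E(y)
  theta <- system$internals$theta_fn(y, E)
  total <- 0
  for (g in gclip) {
    X <- E[g$Erow, , drop = FALSE]
    r <- pmax(system$rules[[g$rule]]$rate(X, g$site, theta[g$site_id], t), 0)
    total <- total + sum(r * y[g$srcP])
  }
  total
}
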