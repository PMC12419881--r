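#' Declare a model dimension
#'
#' A dimension is one discrete degree of freedom of a subsystem (a count of
#' individuals: prey, predators, infectious, recovered, young trees, ...).
#' Counts `0..nc-1` are tracked as explicit master-equation states; counts of
#' `nc` or more are collapsed into a mean-field limit that carries one
#' expected-value equation per combination of the other dimensions' states.
#'
#' @param name Dimension label used in transition stoichiometries and rate
#'   functions.
#' @param nc Nonnegative integer cutoff: number of explicitly tracked states.
#'   With `mf_limit = TRUE` and `nc = 0` the dimension is described purely by
#'   its mean-field value (a classic mean-field description).
#' @param mf_limit If `TRUE` (default), counts `>= nc` are a mean-field
#'   limit. If `FALSE` the state space is hard-truncated at `nc` states
#'   (`0..nc-1`); events that would leave the truncation are dropped. Used
#'   for exact-reference builds.
#' @param pure_mf If `TRUE` the dimension has no explicit states at all,
#'   only a mean-field value per occupation state of the other dimensions
#'   (e.g. seeds and seedlings in the tree lifecycle model). Implies
#'   `nc = 0` and `mf_limit = TRUE`.
#' @return A `meanflame_dimension` object.
#' @export
dimension <- function(name, nc, mf_limit = TRUE, pure_mf = FALSE) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (length(nc) != 1L || is.na(nc) || nc < 0 || nc != round(nc)) {
    stop("`nc` must be a single nonnegative integer")
  }
  if (pure_mf && (nc != 0 || !mf_limit)) {
    stop("a pure mean-field dimension must have nc = 0 and mf_limit = TRUE")
  }
  if (!mf_limit && nc < 1) {
    stop("a hard-truncated dimension needs at least one state (nc >= 1)")
  }
  structure(
    list(name = name, nc = as.integer(nc), mf_limit = isTRUE(mf_limit),
         pure_mf = isTRUE(pure_mf)),
    class = "meanflame_dimension"
  )
}

#' Declare a transition rule
#'
#' A stochastic event with an integer stoichiometry over the model dimensions
#' and a state-dependent rate. Rates must be finite and nonnegative on all
#' reachable states, and must vanish whenever a decremented count is zero
#' (no flow out of empty compartments).
#'
#' @param stoich Named integer vector of count changes, e.g.
#'   `c(prey = -1, pred = 1)` for a predation event.
#' @param rate Function `function(x, site, theta, t)` returning a vector of
#'   rates. `x` is a matrix of effective counts with one column per declared
#'   dimension (explicit coordinates in explicit states, mean-field values
#'   inside a limit); `site` is a list of per-row site covariate vectors
#'   (e.g. `site$N`); `theta` is the per-row cross-subsystem coupling; `t`
#'   the time.
#' @param name Optional label for diagnostics.
#' @return A `meanflame_transition` object.
#' @export
transition <- function(stoich, rate, name = NULL) {
  if (is.null(names(stoich)) || any(!nzchar(names(stoich)))) {
    stop("`stoich` must be a named vector")
  }
  if (any(stoich != round(stoich)) || all(stoich == 0)) {
    stop("`stoich` must be integer and not all zero")
  }
  stopifnot(is.function(rate))
  structure(
    list(stoich = stoich[stoich != 0], rate = rate,
         name = if (is.null(name)) paste(names(stoich), stoich, sep = "",
                                         collapse = ",") else name),
    class = "meanflame_transition"
  )
}

#' Cross-subsystem mean-field coupling
#'
#' Defines the expected-influx field theta: for each subsystem, `factor`
#' times the weighted sum over source subsystems of the expected count of
#' `dimension`. The weight matrix row `i` holds the contribution of every
#' source `j` to subsystem `i`.
#'
#' @param dimension Name of the dimension whose expected count is exported
#'   to neighbours (e.g. infectious individuals, adult trees).
#' @param factor Nonnegative scalar multiplying the weighted sum (a migration
#'   rate lambda, lambda*beta for contact coupling, or a seed production rate).
#' @param weights Square matrix (subsystems x subsystems) of dispersal
#'   weights; `weights[i, j]` weights the expected count of subsystem `j` in
#'   the influx of subsystem `i`.
#' @return A `meanflame_coupling` object.
#' @export
coupling <- function(dimension, factor, weights) {
  stopifnot(is.character(dimension), length(dimension) == 1L)
  if (length(factor) != 1L || is.na(factor) || factor < 0) {
    stop("`factor` must be a single nonnegative value")
  }
  weights <- as.matrix(weights)
  if (nrow(weights) != ncol(weights)) stop("`weights` must be square")
  structure(list(dimension = dimension, factor = factor, weights = weights),
            class = "meanflame_coupling")
}
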