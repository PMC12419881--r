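#' Truncated-Poisson boundary probability
#'
#' Probability that a count drawn from a Poisson distribution with the given
#' mean, conditioned on being at least `nc`, equals exactly `nc`. This is the
#' coupling factor that governs how fast probability leaves a mean-field limit
#' back into the last explicitly tracked master-equation state: a system
#' inside the limit can only step below the cutoff if it currently sits right
#' on the edge of the limit.
#'
#' Computed in log space (`dpois`/`ppois` with `log = TRUE`) so that large
#' means neither overflow `mean^nc` nor underflow the tail sum.
#'
#' As `mean` tends to 0 all conditional mass collapses onto the lower edge of
#' the support, so `rho` tends to 1; `rho(nc, 0)` is defined as 1 for
#' `nc >= 1`. With `nc = 0` the conditioning is vacuous and the value is the
#' plain Poisson mass at zero, `exp(-mean)`.
#'
#' @param nc Nonnegative integer cutoff (edge of the mean-field limit).
#'   Scalar.
#' @param mean Nonnegative Poisson mean (the current mean-field value).
#'   Vectorised.
#' @return Probability in `[0, 1]`, same length as `mean`.
#' @examples
#' rho(0, 1)            # exp(-1)
#' rho(5, 1e-12)        # ~1: conditional mass sits on the edge
#' rho(5, 5)
#' @export
rho <- function(nc, mean) {
  if (length(nc) != 1L || is.na(nc) || nc < 0 || nc != round(nc)) {
    stop("`nc` must be a single nonnegative integer")
  }
  if (any(is.na(mean)) || any(mean < 0)) {
    stop("`mean` must be nonnegative")
  }
  out <- numeric(length(mean))
  zero <- mean == 0
  out[zero] <- 1  # limit mean -> 0+; also exp(0) for nc = 0
  if (any(!zero)) {
    m <- mean[!zero]
    # log P(X = nc) - log P(X >= nc)
    log_num <- stats::dpois(nc, m, log = TRUE)
    log_den <- if (nc == 0) 0 else
      stats::ppois(nc - 1, m, lower.tail = FALSE, log.p = TRUE)
    out[!zero] <- exp(log_num - log_den)
  }
  pmin(pmax(out, 0), 1)
}

#' Truncated-Poisson probability mass function
#'
#' Mass function of a Poisson variable with the given mean conditioned on
#' being at least `nc`; used to expand the occupation probability of a
#' mean-field limit back over integer counts (for marginal distributions and
#' comparisons against exact master equations).
#'
#' @param k Integer counts (vectorised).
#' @param nc Nonnegative integer cutoff; mass is zero below `nc`.
#' @param mean Nonnegative Poisson mean (scalar).
#' @return Probabilities, same length as `k`; zero for `k < nc`.
#' @export
truncated_poisson_pmf <- function(k, nc, mean) {
  if (length(mean) != 1L || is.na(mean) || mean < 0) {
    stop("`mean` must be a single nonnegative value")
  }
  out <- numeric(length(k))
  ok <- k >= nc & k == round(k)
  if (mean == 0) {
    out[ok & k == nc] <- 1
    return(out)
  }
  log_den <- if (nc == 0) 0 else
    stats::ppois(nc - 1, mean, lower.tail = FALSE, log.p = TRUE)
  out[ok] <- exp(stats::dpois(k[ok], mean, log = TRUE) - log_den)
  out
}
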