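# Shared small builds and utilities for the suite.

fig2_p <- bd_params(mu = 1, nu = 0.05, nc = 8L)
fig3_p <- bd_params(mu = 1, nu = 0.1, lam = 0.004, nc = 8L)

# random valid state for conservation checks: occupation from a Dirichlet-ish
# draw, values positive
random_state <- function(sys, seed = 1) {
  set.seed(seed)
  tpl <- sys$tpl
  y <- numeric(sys$n_eq)
  for (s in seq_len(sys$n_sub)) {
    off <- (s - 1L) * tpl$n_per
    if (tpl$keep_occ) {
      p <- stats::rexp(tpl$n_occ)
      y[off + seq_len(tpl$n_occ)] <- p / sum(p)
    }
    y[off + tpl$n_occ + seq_len(tpl$n_val)] <- stats::runif(tpl$n_val, 0, 25)
  }
  y
}

occ_rhs_sum <- function(sys, y, t = 0) {
  dy <- sys$rhs(t, y, NULL)[[1L]]
  tpl <- sys$tpl
  vapply(seq_len(sys$n_sub), function(s)
    sum(dy[(s - 1L) * tpl$n_per + seq_len(tpl$n_occ)]), 0)
}

l1 <- function(a, b) sum(abs(a - b))

# birth-death rules built directly (independent of the model constructors)
bd_rules_for_test <- function(mu, nu) {
  list(transition(c(n = 1), function(x, site, theta, t) mu * x[, "n"]),
       transition(c(n = -1), function(x, site, theta, t) nu * x[, "n"]^2))
}
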