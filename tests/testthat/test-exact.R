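test_that("exact-ME ODE solution matches the matrix-exponential oracle", {
  ex <- build_birth_death_exact(fig2_p, 100L)
  p0 <- numeric(100); p0[2] <- 1
  sol <- integrate_system(ex, p0, integration_config(c(0, 50)))
  pex <- as.vector(Matrix::expm(ex$Q * 50) %*% p0)
  expect_lt(max(abs(solution_state(sol, 50) - pex)), 1e-8)
  # 2-D system too
  lvex <- build_lotka_volterra_exact(lv_params(0.4, 0.04, 0.4, 8, 2))
  q0 <- numeric(lvex$n_eq)
  q0[lvex$states[, "F"] == 3 & lvex$states[, "S"] == 2] <- 1
  sol2 <- integrate_system(lvex, q0, integration_config(c(0, 10)))
  pex2 <- as.vector(Matrix::expm(lvex$Q * 10) %*% q0)
  expect_lt(max(abs(solution_state(sol2, 10) - pex2)), 1e-6)
})

test_that("gillespie respects absorbing states and stoichiometry", {
  ev <- ssa_events(build_birth_death(fig2_p)$rules, "n")
  tr <- gillespie(ev$stoich, ev$rates_fn, c(n = 0), t_end = 10, seed = 7)
  expect_equal(nrow(tr$states), 1L)   # no events out of extinction
  tr2 <- gillespie(ev$stoich, ev$rates_fn, c(n = 5), t_end = 2, seed = 7)
  jumps <- diff(tr2$states[, "n"])
  expect_true(all(jumps %in% c(-1, 1)))
  expect_true(all(diff(tr2$times) > 0))
  # reproducible under the same seed
  tr3 <- gillespie(ev$stoich, ev$rates_fn, c(n = 5), t_end = 2, seed = 7)
  expect_identical(tr2$states, tr3$states)
})

test_that("fraction of first-event extinctions matches nu/(mu+nu)", {
  set.seed(11)
  mu <- 1; nu <- 0.05
  stoich <- matrix(c(1, -1), 2, 1, dimnames = list(NULL, "n"))
  rates <- function(s, t) c(mu * s, nu * s^2)
  n_runs <- 10000L
  died <- vapply(seq_len(n_runs), function(i) {
    tr <- gillespie(stoich, rates, c(n = 1), t_end = Inf, max_events = 1L)
    tr$states[2L, "n"] == 0
  }, TRUE)
  p <- nu / (mu + nu)
  se <- sqrt(p * (1 - p) / n_runs)
  expect_lt(abs(mean(died) - p), 3 * se + 1e-12)
})

test_that("gillespie marginals agree with the exact ME within 3 sigma", {
  set.seed(5)
  p <- bd_params(1, 0.1)                 # metastable state at 10
  ex <- build_birth_death_exact(p, 60L)
  p0 <- numeric(60); p0[2] <- 1
  t_end <- 10
  sol <- integrate_system(ex, p0, integration_config(c(0, t_end)))
  pme <- solution_state(sol, t_end)
  stoich <- matrix(c(1, -1), 2, 1, dimnames = list(NULL, "n"))
  rates <- function(s, t) c(1 * s, 0.1 * s^2)
  n_runs <- 5000L
  finals <- vapply(seq_len(n_runs), function(i)
    gillespie(stoich, rates, c(n = 1), t_end, record = FALSE)[["n"]], 0)
  emp <- tabulate(finals + 1L, nbins = 60L) / n_runs
  # per-state binomial band on states with non-negligible mass
  for (k in which(pme > 1e-3)) {
    se <- sqrt(pme[k] * (1 - pme[k]) / n_runs)
    expect_lt(abs(emp[k] - pme[k]), 3 * se + 1e-9)
  }
  expect_lt(l1(emp, pme), 0.05)
})

test_that("jump-chain absorption probabilities solve the hitting equations", {
  mu <- 1; nu <- 0.05
  rules <- bd_rules_for_test(mu, nu)
  expect_equal(first_passage_absorption(rules, start = 0), 1)
  expect_equal(first_passage_absorption(rules, start = 1), nu / (mu + nu))
  # start = 2: independent closed form for the chain on {1, 2} with failure
  # above 2, allowing re-ascents below the barrier:
  # h1 = p10 + p12 h2,  h2 = p21 h1  =>  h2 = p21 p10 / (1 - p21 p12)
  p21 <- (nu * 4) / (mu * 2 + nu * 4)
  p10 <- nu / (mu + nu)
  p12 <- mu / (mu + nu)
  expect_equal(first_passage_absorption(rules, start = 2),
               p21 * p10 / (1 - p21 * p12), tolerance = 1e-12)
})

test_that("truncation keeps leaked probability negligible at fig2 scale", {
  ex <- build_birth_death_exact(fig2_p, 100L)
  p0 <- numeric(100); p0[2] <- 1
  sol <- integrate_system(ex, p0, integration_config(seq(0, 400, 50)))
  # total probability is conserved to integrator tolerance despite clipping
  expect_lt(max(abs(rowSums(sol$y) - 1)), 1e-7)
  # instantaneous flux that the clipped birth event would carry
  sys <- build_system(dimension("n", 100L, mf_limit = FALSE),
                      build_birth_death(fig2_p)$rules)
  fl <- vapply(seq_along(sol$times), function(i)
    lost_flux(sys, sol$y[i, ]), 0)
  expect_lt(max(fl), 1e-6)
})
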