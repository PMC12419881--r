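test_that("builders reproduce the structural equation counts", {
  expect_equal(count_equations(build_birth_death(bd_params(1, 0.05, nc = 0))), 1L)
  expect_equal(count_equations(build_birth_death(fig2_p)), 10L)
  expect_equal(count_equations(build_birth_death_pair(fig3_p)), 20L)
  expect_equal(build_birth_death_exact(fig2_p, 100L)$n_eq, 100L)
  expect_equal(build_birth_death_pair_exact(fig3_p, 50L)$n_eq, 2500L)
  lv <- build_lotka_volterra(lv_params(0.005, 0.1, 0.1, 20, 3))
  sc <- state_counts(lv)
  expect_equal(sc$explicit, 9L)
  expect_equal(sc$mf_limit, 7L)
  expect_equal(build_lotka_volterra_exact(lv_params(0.005, 0.1, 0.1, 20, 3))$n_eq,
               441L)
  expect_equal(count_equations(build_lotka_volterra(lv_params(0.005, 0.1, 0.1,
                                                              20, 0))), 2L)
})

test_that("equation ordering is deterministic and serialisable", {
  sys <- build_lotka_volterra(lv_params(0.005, 0.1, 0.1, 20, 2))
  tab <- equation_table(sys)
  expect_equal(nrow(tab), count_equations(sys))
  # first dimension varies fastest, MF sentinel last, values after occupations
  expect_equal(tab$label[1:3], c("P[0,0]", "P[1,0]", "P[MF,0]"))
  expect_equal(tab$kind, c(rep("occupation", 9), rep("mf_value", 6)))
  f <- withr::local_tempfile(fileext = ".csv")
  equation_table(sys, f)
  expect_equal(utils::read.csv(f, colClasses = c("integer", "character",
                                                 "integer", "character")),
               tab)
  # identical rebuild enumerates identically
  sys2 <- build_lotka_volterra(lv_params(0.005, 0.1, 0.1, 20, 2))
  expect_identical(sys$labels, sys2$labels)
})

test_that("occupation RHS conserves probability at random states", {
  builds <- list(
    build_birth_death(fig2_p),
    build_birth_death_pair(fig3_p),
    build_lotka_volterra(lv_params(0.005, 0.1, 0.1, 20, 4)),
    build_sirs_site(sirs_params(0.025, 1, 0.01, 0, 5), N = 30),
    build_tree_site(tree_params(nc = 3))
  )
  for (sys in builds) {
    for (seed in 1:3) {
      y <- random_state(sys, seed)
      expect_lt(max(abs(occ_rhs_sum(sys, y, t = 0.7))), 1e-12)
    }
  }
})

test_that("rules referencing undeclared dimensions are rejected", {
  bad <- transition(c(q = 1), function(x, site, theta, t) x[, "q"])
  expect_error(build_system(dimension("n", 3), list(bad)), "undeclared")
  expect_error(dimension("n", -1), "nonnegative")
  expect_error(dimension("s", 2, pure_mf = TRUE), "nc = 0")
})

test_that("mean-field collapse: nc = 0 equals the classic ODE trajectory", {
  # birth-death: dn/dt = mu*n - nu*n^2
  s0 <- build_birth_death(bd_params(1, 0.05, nc = 0))
  y0 <- initial_condition(s0, counts = c(n = 1))
  cfg <- integration_config(seq(0, 400, 4))
  sol <- integrate_system(s0, y0, cfg)
  ref <- deSolve::ode(c(n = 1), cfg$times, function(t, y, p)
    list(1 * y - 0.05 * y^2), NULL, rtol = 1e-10, atol = 1e-12)
  expect_equal(as.vector(sol$y), unname(ref[, 2]), tolerance = 1e-6)
  # Lotka-Volterra n = 0: the two value ODEs are the classic mean-field model
  lv0 <- build_lotka_volterra(lv_params(0.4, 0.04, 0.4, 20, 0))
  ylv <- initial_condition(lv0, counts = c(F = 12, S = 8))
  cfg2 <- integration_config(seq(0, 50, 0.5))
  sol2 <- integrate_system(lv0, ylv, cfg2)
  ref2 <- deSolve::ode(c(F = 12, S = 8), cfg2$times, function(t, y, p) {
    list(c(0.4 * y[1] * (20 - y[1]) - 0.04 * y[1] * y[2],
           0.04 * y[1] * y[2] - 0.4 * y[2]))
  }, NULL, rtol = 1e-10, atol = 1e-12)
  expect_equal(max(abs(sol2$y - ref2[, 2:3])), 0, tolerance = 1e-5)
})

test_that("master-equation collapse: hard-truncated build equals the exact Q", {
  # same state space, independently assembled generator matrices
  sys <- build_system(dimension("n", 40L, mf_limit = FALSE),
                      list(transition(c(n = 1), function(x, site, theta, t)
                             1 * x[, "n"] + theta),
                           transition(c(n = -1), function(x, site, theta, t)
                             0.05 * x[, "n"]^2)))
  ex <- build_birth_death_exact(bd_params(1, 0.05), 40L)
  expect_equal(as.matrix(generator_matrix(sys)), as.matrix(ex$Q),
               tolerance = 1e-14)
  # columns of the generator sum to zero
  expect_lt(max(abs(Matrix::colSums(ex$Q))), 1e-12)
})

test_that("expected counts and coupling are the hand-checkable weighted sums", {
  sys <- build_birth_death(bd_params(1, 0.05, nc = 8))
  # all mass at state 0
  y <- initial_condition(sys, counts = c(n = 0))
  expect_equal(unname(expected_count(sys, y, "n")), 0)
  # all mass in the limit with value 7.3
  y2 <- numeric(sys$n_eq); y2[9] <- 1; y2[10] <- 7.3
  expect_equal(unname(expected_count(sys, y2, "n")), 7.3)
  # mixed mass 0.5 at 0, 0.25 at 2, 0.25 in the limit at 10
  y3 <- numeric(sys$n_eq); y3[1] <- 0.5; y3[3] <- 0.25; y3[9] <- 0.25
  y3[10] <- 10
  expect_equal(unname(expected_count(sys, y3, "n")), 3)
  expect_error(expected_count(sys, y3, "bogus"), "unknown dimension")
  # coupling: factor times summed expected counts, linear in neighbours
  expect_equal(coupling_theta(list(), "n", 0.004), 0)
  expect_equal(coupling_theta(list(system = sys, y = y3), "n", 0.004),
               0.004 * 3)
  expect_equal(coupling_theta(list(list(system = sys, y = y3),
                                   list(system = sys, y = y3)), "n", 0.1),
               0.1 * 6)
})

test_that("hard-truncation clipping is tracked as lost flux", {
  sys <- build_system(dimension("n", 10L, mf_limit = FALSE),
                      list(transition(c(n = 1), function(x, site, theta, t)
                             1 * x[, "n"]),
                           transition(c(n = -1), function(x, site, theta, t)
                             0.05 * x[, "n"]^2)))
  y <- numeric(10); y[10] <- 1           # all mass at the boundary state
  expect_equal(lost_flux(sys, y), 1 * 9)  # birth at n = 9 would leave
  y2 <- numeric(10); y2[1] <- 1
  expect_equal(lost_flux(sys, y2), 0)
})
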