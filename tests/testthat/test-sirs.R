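p_fig8 <- sirs_params(beta = 0.025, alpha = 1, gamma = 0.01, lam = 0.1,
                      nc = 10L)

test_that("per-site equation count follows nc^2 + 4nc + 3", {
  for (nc in 1:12) {
    s <- build_sirs_site(sirs_params(0.025, 1, 0.01, 0, nc), N = 40)
    expect_equal(count_equations(s), nc^2 + 4L * nc + 3L)
  }
})

test_that("grid populations and derived counts match the landscape formula", {
  g <- make_grid(50, 50)
  expect_equal(g$N[g$x == 0 & g$y == 0], 10)        # sin(0) = 0
  im <- which.max(g$N)
  expect_equal(c(g$x[im], g$y[im]), c(0, 3))        # peak near (0, 3)
  expect_equal((max(g$N) + 1L)^2, 12321L)           # full-AME per-site bound
  g1 <- make_grid(1, 1)
  expect_length(g1$neighbors[[1]], 0L)
  # neighbour relation symmetric, no wraparound
  g3 <- make_grid(3, 2)
  expect_true(Matrix::isSymmetric(g3$A))
  expect_equal(vapply(g3$neighbors, length, 0L)[1], 2L)  # corner site
})

test_that("R0 and herd-immunity identities hold for random draws", {
  set.seed(3)
  for (i in 1:20) {
    p <- sirs_params(runif(1, 0.001, 0.2), runif(1, 0.2, 3),
                     runif(1, 0, 0.1))
    N <- sample(1:200, 1)
    d <- epidemic_diagnostics(p, N)
    expect_equal(d$R0, p$beta * N / p$alpha)
    expect_equal(d$h, 1 - 1 / d$R0)
    expect_equal(d$h, 1 - p$alpha / (p$beta * N))
  }
})

test_that("disease-free state is absorbing without coupling", {
  s <- build_sirs_site(p_fig8, N = 30)
  # no occupation probability ever leaves the disease-free state; the value
  # equations evolve autonomously (conditional flows) but carry no mass
  y <- initial_condition(s, counts = c(i = 0, r = 0))
  dy <- s$rhs(0, y, NULL)[[1L]]
  expect_equal(max(abs(dy[seq_len(s$tpl$n_occ)])), 0)
  sol <- integrate_system(s, y, integration_config(seq(0, 9, 1)))
  occ <- sol$y[, seq_len(s$tpl$n_occ)]
  expect_equal(max(abs(occ[, 1] - 1)), 0, tolerance = 1e-9)
})

test_that("uncoupled sites evolve like independent single-site builds", {
  g <- make_grid(2, 1, population = function(x, y) rep(25, length(x)))
  p0 <- sirs_params(0.025, 1, 0.01, lam = 0, nc = 4L)
  meta <- build_sirs_metapopulation(g, p0)
  single <- build_sirs_site(p0, N = 25)
  cfg <- integration_config(seq(0, 9, 0.5))
  ym <- sirs_metapopulation_init(meta, g, c(1L, 1L))
  ys <- initial_condition(single, counts = c(i = 1, r = 0))
  solm <- integrate_system(meta, ym, cfg)
  sols <- integrate_system(single, ys, cfg)
  np <- single$n_eq
  expect_equal(solution_state(solm, 9)[1:np],
               solution_state(solm, 9)[np + 1:np], tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(unname(solution_state(solm, 9)[1:np]),
               unname(solution_state(sols, 9)), tolerance = 1e-9)
})

test_that("case distribution reduces to point mass and convolution limits", {
  g <- make_grid(1, 1, population = function(x, y) 30)
  s <- build_sirs_metapopulation(g, sirs_params(0.025, 1, 0.01, 0, 3L))
  y <- sirs_metapopulation_init(s, g, 0L)
  sol <- structure(list(times = 0, y = matrix(y, 1), system = s),
                   class = "meanflame_solution")
  d <- case_distribution(sol, 1, 0)
  expect_equal(d, c(1, rep(0, 30)))
  # site fully in the double limit: sum of two independent truncated Poissons
  tpl <- s$tpl
  y2 <- numeric(s$n_eq)
  dbl <- tpl$state_id(c(4L, 4L))
  y2[dbl] <- 1
  vi <- tpl$n_occ + tpl$val_id("i", c(4L, 4L))
  vr <- tpl$n_occ + tpl$val_id("r", c(4L, 4L))
  y2[vi] <- 5; y2[vr] <- 4
  sol2 <- structure(list(times = 0, y = matrix(y2, 1), system = s),
                    class = "meanflame_solution")
  d2 <- case_distribution(sol2, 1, 0, max_count = 60)
  di <- truncated_poisson_pmf(0:60, 3, 5)
  dr <- truncated_poisson_pmf(0:60, 3, 4)
  conv <- stats::convolve(di, rev(dr), type = "open")[1:61]
  expect_equal(d2[1:40], conv[1:40], tolerance = 1e-10)
  expect_equal(sum(d2), 1, tolerance = 1e-9)
})

test_that("introduction times are trivially 0 / Inf at the endpoints", {
  g <- make_grid(2, 1, population = function(x, y) rep(25, length(x)))
  p0 <- sirs_params(0.025, 1, 0.01, lam = 0, nc = 4L)
  meta <- build_sirs_metapopulation(g, p0)
  ym <- sirs_metapopulation_init(meta, g, c(1L, 0L))
  sol <- integrate_system(meta, ym, integration_config(seq(0, 9, 0.5)))
  expect_equal(time_to_introduction(sol, 1, 0.5), 0)   # seeded site
  expect_equal(time_to_introduction(sol, 2, 0.5), Inf) # unreachable: lam = 0
})

test_that("introduction time grows with distance on a homogeneous lattice", {
  g <- make_grid(5, 1, population = function(x, y) rep(50, length(x)))
  p <- sirs_params(0.05, 1, 0.01, lam = 0.5, nc = 6L)
  meta <- build_sirs_metapopulation(g, p)
  ym <- sirs_metapopulation_init(meta, g, c(2L, 0L, 0L, 0L, 0L))
  sol <- integrate_system(meta, ym, integration_config(seq(0, 30, 0.25)))
  tt <- vapply(1:5, function(s) time_to_introduction(sol, s, 0.4), 0)
  expect_true(all(is.finite(tt)))
  expect_true(all(diff(tt) > 0))
  # cross-check ordering against Gillespie first-arrival times
  set.seed(21)
  A <- as.matrix(g$A)
  n_runs <- 300L
  arrivals <- matrix(Inf, n_runs, 5)
  for (run in seq_len(n_runs)) {
    i <- c(2L, 0L, 0L, 0L, 0L); r <- integer(5); t <- 0
    seen <- c(0, rep(Inf, 4))
    repeat {
      rates <- c((p$beta * i + p$lam * p$beta * as.vector(A %*% i)) *
                   pmax(50 - i - r, 0), p$alpha * i, p$gamma * r)
      tot <- sum(rates)
      if (tot <= 0 || t > 30) break
      t <- t + rexp(1, tot)
      if (t > 30) break
      ev <- sample.int(15L, 1L, prob = rates)
      site <- (ev - 1L) %% 5L + 1L; type <- (ev - 1L) %/% 5L + 1L
      if (type == 1L) { i[site] <- i[site] + 1L
        seen[site] <- min(seen[site], t) }
      else if (type == 2L) { i[site] <- i[site] - 1L; r[site] <- r[site] + 1L }
      else r[site] <- r[site] - 1L
    }
    arrivals[run, ] <- seen
  }
  med <- apply(arrivals, 2, stats::median)
  expect_true(all(diff(med) > 0))
  expect_equal(order(tt), order(med))
})
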