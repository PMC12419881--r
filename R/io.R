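#' Run a model from a declarative configuration
#'
#' Builds, optionally integrates or simulates, writes tabular outputs and a
#' JSON run manifest (config snapshot, seed, equation counts, integrator
#' diagnostics, package version). The configuration is a flat list (or a
#' YAML file path) with a `model` key naming one of `birth-death`,
#' `birth-death-pair`, `lotka-volterra`, `sirs`, `trees`, a `params`
#' section, and model-specific keys (`t_end`, `start`, `grid`, ...).
#'
#' @param config Path to a YAML file or a configuration list.
#' @param action One of `"build"` (count equations only), `"integrate"`,
#'   `"simulate"` (Gillespie; birth-death and sirs), `"compare"`
#'   (mean-FLAME vs exact reference; birth-death and lotka-volterra).
#' @param out_dir Output directory (created if missing).
#' @param seed Integer seed for stochastic actions; recorded in the
#'   manifest.
#' @return Invisibly, the manifest list.
#' @export
run_from_config <- function(config, action = "integrate",
                            out_dir = tempfile("meanflame_run_"),
                            seed = 1L) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  # tolerate round-tripped configs where sections came back as named vectors
  for (k in c("params", "start", "grid")) {
    if (!is.null(config[[k]])) config[[k]] <- as.list(config[[k]])
  }
  if (!is.list(config) || is.null(config$model)) {
    stop("config must provide keys: model (one of birth-death, ",
         "birth-death-pair, lotka-volterra, sirs, trees), params")
  }
  action <- match.arg(action, c("build", "integrate", "simulate", "compare"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  need <- function(keys, where = config) {
    miss <- setdiff(keys, names(where))
    if (length(miss)) stop("config missing required key(s): ",
                           paste(miss, collapse = ", "))
  }
  need("params")
  p <- config$params
  t_end <- config$t_end %||% 100
  times <- seq(0, t_end, length.out = config$n_times %||% 101L)
  cfgi <- integration_config(times,
                             rtol = config$rtol %||% 1e-8,
                             atol = config$atol %||% 1e-10,
                             method = config$method %||% "lsoda")
  manifest <- list(config = config, action = action, seed = seed,
                   version = as.character(utils::packageVersion("meanflame")),
                   outputs = character(0))
  add_out <- function(nm) manifest$outputs <<- c(manifest$outputs, nm)
  write_traj <- function(sol, nm) {
    df <- data.frame(time = sol$times, sol$y)
    names(df) <- c("time", sol$system$labels)
    utils::write.csv(df, file.path(out_dir, nm), row.names = FALSE)
    add_out(nm)
  }

  if (config$model == "birth-death") {
    need(c("mu", "nu", "nc"), p)
    params <- bd_params(p$mu, p$nu, p$lam %||% 0, p$nc)
    sys <- build_birth_death(params)
    manifest$equation_count <- count_equations(sys)
    start <- config$start$n %||% 1
    if (action %in% c("integrate", "compare")) {
      y0 <- initial_condition(sys, counts = c(n = start))
      sol <- integrate_system(sys, y0, cfgi)
      manifest$diagnostics <- sol$diagnostics
      write_traj(sol, "trajectory.csv")
    }
    if (action == "simulate") {
      set.seed(seed)
      ev <- ssa_events(sys$rules, "n")
      tr <- gillespie(ev$stoich, ev$rates_fn, c(n = start), t_end)
      df <- data.frame(time = tr$times, tr$states)
      utils::write.csv(df, file.path(out_dir, "events.csv"),
                       row.names = FALSE)
      add_out("events.csv")
    }
    if (action == "compare") {
      ex <- build_birth_death_exact(params, config$exact_states %||% 100L)
      manifest$exact_equation_count <- ex$n_eq
      p0 <- numeric(ex$n_eq); p0[start + 1L] <- 1
      sole <- integrate_system(ex, p0, cfgi)
      mx <- ex$n_eq - 1L
      dist_h <- marginal_distribution(sys, solution_state(sol, t_end), "n", mx)
      dist_e <- solution_state(sole, t_end)
      df <- data.frame(n = 0:mx, hybrid = dist_h, exact = as.vector(dist_e))
      utils::write.csv(df, file.path(out_dir, "distribution_comparison.csv"),
                       row.names = FALSE)
      add_out("distribution_comparison.csv")
      manifest$l1_distance <- sum(abs(dist_h - dist_e))
    }
  } else if (config$model == "birth-death-pair") {
    need(c("mu", "nu", "lam", "nc"), p)
    params <- bd_params(p$mu, p$nu, p$lam, p$nc)
    sys <- build_birth_death_pair(params)
    manifest$equation_count <- count_equations(sys)
    if (action != "build") {
      y0 <- initial_condition(sys, counts = c(n = config$start$n %||% 1))
      sol <- integrate_system(sys, y0, cfgi)
      manifest$diagnostics <- sol$diagnostics
      write_traj(sol, "trajectory.csv")
    }
  } else if (config$model == "lotka-volterra") {
    need(c("mu", "nu", "beta", "K", "n"), p)
    params <- lv_params(p$mu, p$beta, p$nu, p$K, p$n)
    sys <- build_lotka_volterra(params)
    manifest$equation_count <- count_equations(sys)
    ex <- build_lotka_volterra_exact(params)
    manifest$exact_equation_count <- ex$n_eq
    start <- c(F = config$start$F %||% 1, S = config$start$S %||% 1)
    if (action != "build") {
      y0 <- initial_condition(sys, counts = start)
      sol <- integrate_system(sys, y0, cfgi)
      manifest$diagnostics <- sol$diagnostics
      curve <- extinction_probability(sol)
      utils::write.csv(curve, file.path(out_dir, "extinction_curve.csv"),
                       row.names = FALSE)
      add_out("extinction_curve.csv")
    }
    if (action == "compare") {
      p0 <- numeric(ex$n_eq)
      p0[ex$states[, "F"] == start["F"] & ex$states[, "S"] == start["S"]] <- 1
      sole <- integrate_system(ex, p0, cfgi)
      ce <- extinction_probability(sole)
      df <- data.frame(time = curve$time, meanflame = curve$p_extinct,
                       exact = ce$p_extinct)
      utils::write.csv(df, file.path(out_dir, "extinction_comparison.csv"),
                       row.names = FALSE)
      add_out("extinction_comparison.csv")
      manifest$extinction_sup_gap <- max(abs(df$meanflame - df$exact))
    }
  } else if (config$model == "sirs") {
    need(c("beta", "alpha", "gamma", "lam", "nc"), p)
    need("grid")
    params <- sirs_params(p$beta, p$alpha, p$gamma, p$lam, p$nc)
    grid <- make_grid(config$grid$width, config$grid$height)
    lazy <- isTRUE(config$lazy) || action == "build"
    sys <- build_sirs_metapopulation(grid, params, lazy = lazy)
    manifest$equation_count <- count_equations(sys)
    seeded <- grid$x < 5 & grid$y < 5
    inf0 <- ifelse(seeded, config$initial_infections %||% 1L, 0L)
    if (action == "integrate") {
      y0 <- sirs_metapopulation_init(sys, grid, inf0)
      sol <- integrate_system(sys, y0, cfgi)
      manifest$diagnostics <- sol$diagnostics
      cases <- vapply(seq_len(grid$n_sites), function(s)
        sum((0:grid$N[s]) * case_distribution(sol, s, t_end)), 0)
      intro <- vapply(seq_len(grid$n_sites), function(s)
        time_to_introduction(sol, s), 0)
      df <- data.frame(x = grid$x, y = grid$y, N = grid$N,
                       expected_cases = cases, time_to_introduction = intro)
      utils::write.csv(df, file.path(out_dir, "site_summary.csv"),
                       row.names = FALSE)
      add_out("site_summary.csv")
    }
    if (action == "simulate") {
      cs <- sirs_gillespie_cases(grid, params, inf0, t_end,
                                 config$n_runs %||% 1000L, seed = seed)
      utils::write.csv(as.data.frame(cs), file.path(out_dir, "cases.csv"),
                       row.names = FALSE)
      add_out("cases.csv")
    }
  } else if (config$model == "trees") {
    need(c("mu_a", "mu_s", "nu_s", "mu_g", "nu_g", "mu_y", "nu_y", "nu_a",
           "nc"), p)
    need("grid")
    params <- tree_params(p$mu_a, p$mu_s, p$nu_s, p$mu_g, p$nu_g, p$mu_y,
                          p$nu_y, p$nu_a, p$nc)
    grid <- make_grid(config$grid$width, config$grid$height,
                      population = NULL)
    lazy <- isTRUE(config$lazy) || action == "build"
    sys <- build_tree_landscape(grid, params, lazy = lazy)
    manifest$equation_count <- count_equations(sys)
    if (action != "build") {
      seeded <- grid$x < 5 & grid$y < 5
      y0 <- tree_init(sys, grid, config$seeds %||% 10,
                      config$seedlings %||% 20, seeded)
      out_t <- config$output_times %||% t_end
      cfgi$times <- sort(unique(c(cfgi$times, out_t)))
      sol <- integrate_system(sys, y0, cfgi)
      manifest$diagnostics <- sol$diagnostics
      for (tt in out_t) {
        df <- data.frame(x = grid$x, y = grid$y,
                         expected_adults = adult_map(sol, tt))
        nm <- paste0("adults_t", tt, ".csv")
        utils::write.csv(df, file.path(out_dir, nm), row.names = FALSE)
        add_out(nm)
      }
    }
  } else {
    stop("unknown model '", config$model, "'; expected one of birth-death, ",
         "birth-death-pair, lotka-volterra, sirs, trees")
  }

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       null = "null")
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
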