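#' Tree lifecycle parameters
#'
#' Four-stage lifecycle: seeds (s) and seedlings (g) are pure mean-field
#' dimensions (no explicit states, one value per occupation state), while
#' saplings/young trees (y) and adults (a) -- the stochastic bottlenecks of
#' the lifecycle -- are tracked with explicit master-equation states plus
#' mean-field limits. Each stage dies at its own rate and matures into the
#' next stage; sapling growth into adults is nonlinear, at rate
#' `mu_y * sqrt(y) * max(K - a, 0)` with the climate-driven carrying
#' capacity K capping adults.
#'
#' @param mu_a Seed production rate per adult tree.
#' @param mu_s,nu_s Seed maturation and death rates.
#' @param mu_g,nu_g Seedling maturation and death rates.
#' @param mu_y,nu_y Sapling growth coefficient and death rate.
#' @param nu_a Adult death rate.
#' @param nc Explicit states for the young and adult dimensions.
#' @return A parameter list of class `tree_params`.
#' @export
tree_params <- function(mu_a = 1000, mu_s = 0.5, nu_s = 20, mu_g = 0.2,
                        nu_g = 1, mu_y = 0.1, nu_y = 0.5, nu_a = 0.05,
                        nc = 5L) {
  p <- list(mu_a = mu_a, mu_s = mu_s, nu_s = nu_s, mu_g = mu_g,
            nu_g = nu_g, mu_y = mu_y, nu_y = nu_y, nu_a = nu_a,
            nc = as.integer(nc))
  stopifnot(all(unlist(p) >= 0))
  structure(p, class = "tree_params")
}

#' Climate-driven carrying capacity
#'
#' The drifting suitability landscape
#' `K(x, y, t) = 20 * (sin((x + t)/2) * cos((y + t)/5))^2`: local capacity
#' oscillates between 0 and 20 and the suitable patches drift diagonally
#' with time.
#'
#' @param x,y Site coordinates (vectorised).
#' @param t Time.
#' @return Carrying capacities in `[0, 20]`.
#' @export
climate_capacity <- function(x, y, t) {
  20 * (sin((x + t) / 2) * cos((y + t) / 5))^2
}

tree_rules <- function(p, K_of_t) {
  list(
    transition(c(s = 1), function(x, site, theta, t) theta, "seed influx"),
    transition(c(s = -1), function(x, site, theta, t)
      p$nu_s * x[, "s"], "seed death"),
    transition(c(s = -1, g = 1), function(x, site, theta, t)
      p$mu_s * x[, "s"], "seed maturation"),
    transition(c(g = -1), function(x, site, theta, t)
      p$nu_g * x[, "g"], "seedling death"),
    transition(c(g = -1, y = 1), function(x, site, theta, t)
      p$mu_g * x[, "g"], "sapling arrival"),
    transition(c(y = -1), function(x, site, theta, t)
      p$nu_y * x[, "y"], "sapling death"),
    transition(c(y = -1, a = 1), function(x, site, theta, t)
      p$mu_y * sqrt(pmax(x[, "y"], 0)) *
        pmax(K_of_t(site$x, site$y, t) - x[, "a"], 0), "growth"),
    transition(c(a = -1), function(x, site, theta, t)
      p$nu_a * x[, "a"], "adult death")
  )
}

tree_dims <- function(nc) {
  list(dimension("y", nc), dimension("a", nc),
       dimension("s", 0L, pure_mf = TRUE), dimension("g", 0L, pure_mf = TRUE))
}

# source-normalised uniform dispersal: each site spreads its seed output
# evenly over itself and its available von Neumann neighbours
tree_dispersal_weights <- function(grid) {
  deg <- vapply(grid$neighbors, length, 0L)
  W <- grid$A + Matrix::Diagonal(grid$n_sites)
  W %*% Matrix::Diagonal(grid$n_sites, 1 / (deg + 1))
}

#' Single-site tree lifecycle build
#'
#' Events on the (young, adult) lattice: sapling arrival (+1 y at rate
#' `mu_g * G` of the state's seedling value), sapling death, growth
#' (-1 y, +1 a at the square-root rate), adult death; seed and seedling
#' value ODEs per occupation state (`dS/dt = influx - (mu_s + nu_s) S`,
#' `dG/dt = mu_s S - (mu_g + nu_g) G`). Seed influx is the dispersal
#' coupling `mu_a` times the expected adult count (self weight 1 for an
#' isolated site).
#'
#' @param params A [tree_params()].
#' @param K_of_t Carrying-capacity function `(x, y, t)`; defaults to
#'   [climate_capacity()].
#' @param x,y Site coordinates fed to `K_of_t`.
#' @return A `meanflame_system`.
#' @export
build_tree_site <- function(params, K_of_t = climate_capacity, x = 0, y = 0) {
  stopifnot(inherits(params, "tree_params"))
  build_system(tree_dims(params$nc), tree_rules(params, K_of_t),
               couple = coupling("a", params$mu_a, matrix(1, 1L, 1L)),
               site = list(x = x, y = y))
}

#' Tree-dispersal landscape build
#'
#' One lifecycle system per lattice site; seeds are distributed from each
#' site uniformly over itself and its von Neumann neighbours (weights
#' renormalised at the boundary), so the seed influx of a site is
#' `mu_a * sum over sources of w * E[adults]`.
#'
#' @param grid A [make_grid()] (populations not needed).
#' @param params A [tree_params()].
#' @param K_of_t Carrying-capacity function `(x, y, t)`.
#' @param lazy If `TRUE`, enumerate only.
#' @return A `meanflame_system` with one subsystem per site.
#' @export
build_tree_landscape <- function(grid, params, K_of_t = climate_capacity,
                                 lazy = FALSE) {
  stopifnot(inherits(grid, "meanflame_grid"))
  build_system(tree_dims(params$nc), tree_rules(params, K_of_t),
               n_sub = grid$n_sites,
               couple = coupling("a", params$mu_a,
                                 tree_dispersal_weights(grid)),
               site = list(x = grid$x, y = grid$y),
               lazy = lazy)
}

#' Classic mean-field tree comparator
#'
#' The same lifecycle with `nc = 0`: four deterministic value equations per
#' site (seeds, seedlings, young, adults), where the square-root growth
#' nonlinearity acts on the continuous expected sapling count -- the
#' construction that artificially boosts the growth of the first young
#' trees and overestimates the speed of spatial diffusion.
#'
#' @inheritParams build_tree_landscape
#' @return A `meanflame_system` (4 equations per site).
#' @export
build_tree_meanfield <- function(grid, params, K_of_t = climate_capacity,
                                 lazy = FALSE) {
  p0 <- params; p0$nc <- 0L
  build_tree_landscape(grid, p0, K_of_t, lazy = lazy)
}

#' Initial state for tree builds
#'
#' No trees anywhere; the given seed and seedling stocks in the sites
#' selected by `seeded` (defaults: none).
#'
#' @param system A tree `meanflame_system`.
#' @param grid The grid it was built on (omit for single-site builds).
#' @param seeds,seedlings Initial stocks in seeded sites.
#' @param seeded Logical vector of seeded sites.
#' @return Numeric state vector.
#' @export
tree_init <- function(system, grid = NULL, seeds = 10, seedlings = 20,
                      seeded = NULL) {
  n <- system$n_sub
  sv <- numeric(n); gv <- numeric(n)
  if (is.null(seeded)) seeded <- rep(TRUE, n)
  sv[seeded] <- seeds; gv[seeded] <- seedlings
  initial_condition(system, counts = c(y = 0, a = 0),
                    values = list(s = sv, g = gv))
}

#' Expected adult trees per site
#'
#' @param sol A `meanflame_solution` of a tree build.
#' @param t Time on the solution grid.
#' @return Numeric vector of expected adult counts per site.
#' @export
adult_map <- function(sol, t) {
  y <- solution_state(sol, t)
  expected_count(sol$system, y, "a")
}
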