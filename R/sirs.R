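#' SIRS model parameters
#'
#' Closed local populations of size N where susceptibles are infected at
#' rate `(beta*i + theta) * s` (with `s = N - i - r` and `theta` the spatial
#' coupling), infectious individuals recover at rate `alpha * i`, and
#' immunity wanes at rate `gamma * r`. The local state is the pair (i, r).
#'
#' @param beta Per-contact infection rate.
#' @param alpha Recovery rate.
#' @param gamma Waning rate.
#' @param lam Spatial coupling factor (the coupling is `lam * beta` times
#'   the neighbours' expected infectious counts).
#' @param nc Explicit states per dimension (both i and r).
#' @return A parameter list of class `sirs_params`.
#' @export
sirs_params <- function(beta, alpha, gamma, lam = 0, nc = 10L) {
  stopifnot(beta >= 0, alpha >= 0, gamma >= 0, lam >= 0, nc >= 0)
  structure(list(beta = beta, alpha = alpha, gamma = gamma, lam = lam,
                 nc = as.integer(nc)),
            class = "sirs_params")
}

sirs_rules <- function(beta, alpha, gamma) {
  list(
    transition(c(i = 1), function(x, site, theta, t)
      (beta * x[, "i"] + theta) * pmax(site$N - x[, "i"] - x[, "r"], 0),
      "infection"),
    transition(c(i = -1, r = 1), function(x, site, theta, t)
      alpha * x[, "i"], "recovery"),
    transition(c(r = -1), function(x, site, theta, t)
      gamma * x[, "r"], "waning")
  )
}

#' Rectangular metapopulation lattice
#'
#' Sites at integer coordinates `x in 0..width-1`, `y in 0..height-1`,
#' connected to their von Neumann neighbours (no wraparound). The default
#' population surface is the heterogeneous landscape
#' `N(x, y) = ceiling(10 + 100 * cos(x/5)^2 * sin(y/2)^2)`.
#'
#' @param width,height Grid extent (sites per axis).
#' @param population Function of `(x, y)` returning the local population
#'   size, or a vector/matrix of populations, or `NULL` (population-free
#'   grid, e.g. for the tree model).
#' @return A `meanflame_grid`: list with `x`, `y`, `N`, `n_sites`,
#'   adjacency matrix `A`, neighbour list `neighbors`, and `dims`.
#' @export
make_grid <- function(width, height,
                      population = function(x, y)
                        ceiling(10 + 100 * cos(x / 5)^2 * sin(y / 2)^2)) {
  stopifnot(width >= 1, height >= 1)
  xy <- expand.grid(x = 0:(width - 1L), y = 0:(height - 1L))
  n <- nrow(xy)
  idx <- function(x, y) x + width * y + 1L
  nb <- vector("list", n)
  ii <- integer(0); jj <- integer(0)
  for (s in seq_len(n)) {
    x <- xy$x[s]; y <- xy$y[s]
    cand <- rbind(c(x + 1, y), c(x - 1, y), c(x, y + 1), c(x, y - 1))
    keep <- cand[, 1] >= 0 & cand[, 1] < width &
            cand[, 2] >= 0 & cand[, 2] < height
    nb[[s]] <- idx(cand[keep, 1], cand[keep, 2])
    ii <- c(ii, rep(s, sum(keep))); jj <- c(jj, nb[[s]])
  }
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = 1, dims = c(n, n))
  N <- NULL
  if (!is.null(population)) {
    N <- if (is.function(population)) population(xy$x, xy$y)
         else rep(as.vector(population), length.out = n)
    if (any(N < 1) || any(N != round(N))) stop("populations must be positive integers")
  }
  structure(list(x = xy$x, y = xy$y, N = N, n_sites = n,
                 A = A, neighbors = nb, width = width, height = height),
            class = "meanflame_grid")
}

#' @export
print.meanflame_grid <- function(x, ...) {
  cat("lattice:", x$width, "x", x$height, "(", x$n_sites, "sites )\n")
  if (!is.null(x$N)) {
    im <- which.max(x$N)
    cat("  population: max", x$N[im], "at (x=", x$x[im], ", y=", x$y[im],
        "); total", sum(x$N), "\n")
  }
  invisible(x)
}

#' Reproduction number and herd-immunity threshold
#'
#' `R0 = beta * N / alpha` and `h = 1 - 1/R0 = 1 - alpha/(beta*N)` per
#' site; `h` may be negative for subcritical sites.
#'
#' @param params An [sirs_params()].
#' @param N Population size(s).
#' @return Data frame with `N`, `R0` and `h`.
#' @export
epidemic_diagnostics <- function(params, N) {
  R0 <- params$beta * N / params$alpha
  data.frame(N = N, R0 = R0, h = 1 - 1 / R0)
}

#' Single-site SIRS build
#'
#' Two-dimensional hybrid build over (infectious, recovered) with events
#' infection (+1 i), recovery (-1 i, +1 r) and waning (-1 r). For
#' `nc >= 1` the per-site equation count is `nc^2 + 4*nc + 3`.
#'
#' @param params An [sirs_params()].
#' @param N Local population size.
#' @return A `meanflame_system`.
#' @export
build_sirs_site <- function(params, N) {
  stopifnot(inherits(params, "sirs_params"), N >= 1)
  build_system(list(dimension("i", params$nc), dimension("r", params$nc)),
               sirs_rules(params$beta, params$alpha, params$gamma),
               site = list(N = N))
}

#' Spatial SIRS metapopulation build
#'
#' One hybrid site system per lattice site, joined through the
#' expected-influx field `theta(x, y) = lam * beta * sum over neighbours of
#' the expected infectious count` (explicit states, infectious mean-field
#' limits and the double limit all contribute), recomputed at every
#' right-hand-side evaluation.
#'
#' @param grid A [make_grid()] with populations.
#' @param params An [sirs_params()].
#' @param lazy If `TRUE`, enumerate only (for equation counting of large
#'   grids).
#' @return A `meanflame_system` with one subsystem per site.
#' @export
build_sirs_metapopulation <- function(grid, params, lazy = FALSE) {
  stopifnot(inherits(grid, "meanflame_grid"), !is.null(grid$N))
  build_system(list(dimension("i", params$nc), dimension("r", params$nc)),
               sirs_rules(params$beta, params$alpha, params$gamma),
               n_sub = grid$n_sites,
               couple = coupling("i", params$lam * params$beta, grid$A),
               site = list(N = grid$N),
               lazy = lazy)
}

#' Classic mean-field SIRS comparator
#'
#' Three deterministic ODEs per site for the expected numbers of
#' susceptible, infectious and recovered individuals, coupled through the
#' same expected-influx field. Readouts assume a Poisson distribution
#' around the tracked averages (see [case_distribution()]).
#'
#' @inheritParams build_sirs_metapopulation
#' @return An object with `$rhs`, `$n_eq`, `$labels` usable by
#'   [integrate_system()], of class `sirs_meanfield`.
#' @export
build_sirs_meanfield <- function(grid, params) {
  stopifnot(inherits(grid, "meanflame_grid"), !is.null(grid$N))
  n <- grid$n_sites
  A <- grid$A; N <- grid$N
  beta <- params$beta; alpha <- params$alpha; gamma <- params$gamma
  lb <- params$lam * params$beta
  # layout: per site (s, i, r), site-major
  si <- 3L * (seq_len(n) - 1L)
  rhs <- function(t, y, parms) {
    s <- y[si + 1L]; i <- y[si + 2L]; r <- y[si + 3L]
    theta <- lb * as.vector(A %*% i)
    inf <- (beta * i + theta) * pmax(s, 0)
    rec <- alpha * i
    wan <- gamma * r
    dy <- numeric(3L * n)
    dy[si + 1L] <- -inf + wan
    dy[si + 2L] <- inf - rec
    dy[si + 3L] <- rec - wan
    list(dy)
  }
  labels <- paste0("s", rep(seq_len(n), each = 3L), ":",
                   rep(c("S", "I", "R"), n))
  structure(list(rhs = rhs, n_eq = 3L * n, labels = labels, grid = grid,
                 params = params, site_offset = si),
            class = "sirs_meanfield")
}

#' Initial state for the mean-field SIRS comparator
#'
#' @param mf A `sirs_meanfield` build.
#' @param infections Integer vector of initial infectious individuals per
#'   site.
#' @return Numeric state vector (s, i, r per site).
#' @export
sirs_meanfield_init <- function(mf, infections) {
  n <- mf$grid$n_sites
  infections <- rep(infections, length.out = n)
  if (any(infections > mf$grid$N)) stop("initial infections exceed local N")
  y <- numeric(3L * n)
  y[mf$site_offset + 1L] <- mf$grid$N - infections
  y[mf$site_offset + 2L] <- infections
  y
}

#' Initial state for a metapopulation build
#'
#' Point mass on (i = infections, r = 0) per site.
#'
#' @param system The metapopulation `meanflame_system`.
#' @param grid The grid it was built on.
#' @param infections Integer vector (per site) of initial infectious
#'   individuals.
#' @return Numeric state vector.
#' @export
sirs_metapopulation_init <- function(system, grid, infections) {
  infections <- rep(infections, length.out = grid$n_sites)
  if (any(infections > grid$N)) stop("initial infections exceed local N")
  initial_condition(system,
                    counts = cbind(i = infections, r = 0))
}

#' Distribution of cases at a site
#'
#' Marginal distribution of the case count `c = i + r` at one site of a
#' solved trajectory. Mean-field-limit mass is expanded over integer counts
#' with the truncated-Poisson shapes implied by the current limit values;
#' the double limit contributes the convolution of two independent
#' truncated Poissons. For a `sirs_meanfield` solution the readout is a
#' Poisson distribution around the tracked average cases.
#'
#' @param sol A `meanflame_solution`.
#' @param site Site index.
#' @param t Time on the solution grid.
#' @param max_count Support upper end (defaults to the local population).
#' @return Numeric vector of probabilities over counts `0..max_count`
#'   (tail mass beyond the support is folded into the last bin).
#' @export
case_distribution <- function(sol, site, t, max_count = NULL) {
  sys <- sol$system
  y <- solution_state(sol, t)
  if (inherits(sys, "sirs_meanfield")) {
    if (is.null(max_count)) max_count <- sys$grid$N[site]
    mc <- y[sys$site_offset[site] + 2L] + y[sys$site_offset[site] + 3L]
    p <- stats::dpois(0:max_count, max(mc, 0))
    p[max_count + 1L] <- p[max_count + 1L] +
      stats::ppois(max_count, max(mc, 0), lower.tail = FALSE)
    return(unname(p))
  }
  stopifnot(inherits(sys, "meanflame_system"))
  tpl <- sys$tpl
  if (is.null(max_count)) {
    max_count <- if (length(sys$site$N)) sys$site$N[site] else
      stop("`max_count` required")
  }
  off <- (site - 1L) * tpl$n_per
  ki <- match("i", tpl$exp_names); kr <- match("r", tpl$exp_names)
  supp <- 0:max_count
  big <- 4L * max_count + 40L    # working support before folding
  out_big <- numeric(big + 1L)
  for (s in seq_len(tpl$n_states)) {
    p <- y[off + s]
    if (p <= 0) next
    i_mf <- tpl$state_is_mf[s, ki]; r_mf <- tpl$state_is_mf[s, kr]
    di <- if (i_mf) {
      v <- max(y[off + tpl$n_occ + tpl$val_id("i", tpl$states[s, ])], 0)
      truncated_poisson_pmf(0:big, tpl$nc[ki], v)
    } else NULL
    dr <- if (r_mf) {
      v <- max(y[off + tpl$n_occ + tpl$val_id("r", tpl$states[s, ])], 0)
      truncated_poisson_pmf(0:big, tpl$nc[kr], v)
    } else NULL
    if (!i_mf && !r_mf) {
      cc <- (tpl$states[s, ki] - 1L) + (tpl$states[s, kr] - 1L)
      out_big[min(cc, big) + 1L] <- out_big[min(cc, big) + 1L] + p
    } else if (i_mf && !r_mf) {
      r0 <- tpl$states[s, kr] - 1L
      shifted <- c(numeric(r0), di)[1:(big + 1L)]
      out_big <- out_big + p * shifted
    } else if (!i_mf && r_mf) {
      i0 <- tpl$states[s, ki] - 1L
      shifted <- c(numeric(i0), dr)[1:(big + 1L)]
      out_big <- out_big + p * shifted
    } else {
      conv <- stats::convolve(di, rev(dr), type = "open")[1:(big + 1L)]
      out_big <- out_big + p * pmax(conv, 0)
    }
  }
  out <- out_big[seq_len(max_count + 1L)]
  out[max_count + 1L] <- out[max_count + 1L] +
    sum(out_big[-seq_len(max_count + 1L)])
  unname(out)
}

#' Time to introduction at a site
#'
#' First time on the solution grid at which the probability of at least one
#' infectious individual at the site reaches the threshold; `Inf` if never.
#'
#' @param sol A `meanflame_solution` of a metapopulation build.
#' @param site Site index.
#' @param threshold Probability threshold in (0, 1).
#' @return Time (possibly `Inf`).
#' @export
time_to_introduction <- function(sol, site, threshold = 0.5) {
  stopifnot(threshold > 0, threshold < 1)
  sys <- sol$system
  stopifnot(inherits(sys, "meanflame_system"))
  tpl <- sys$tpl
  ki <- match("i", tpl$exp_names)
  zero_i <- which(tpl$states[, ki] == 1L & !tpl$state_is_mf[, ki])
  idx <- (site - 1L) * tpl$n_per + zero_i
  p_active <- 1 - rowSums(sol$y[, idx, drop = FALSE])
  hit <- which(p_active >= threshold)
  if (!length(hit)) Inf else sol$times[hit[1L]]
}

#' Ensemble Gillespie simulation of the spatial SIRS process
#'
#' Statistically exact simulation of the full joint metapopulation process
#' (infection at rate `(beta*i + lam*beta*sum of neighbour i) * s` per
#' site, recovery, waning), vectorised over sites. Returns the case counts
#' `i + r` per site at the requested time across runs.
#'
#' @param grid A [make_grid()] with populations.
#' @param params An [sirs_params()].
#' @param infections Initial infectious individuals per site.
#' @param t Time at which cases are recorded.
#' @param n_runs Number of independent realisations.
#' @param seed Integer seed (recorded on the result).
#' @return Integer matrix `n_runs x n_sites` of case counts, with the seed
#'   as attribute.
#' @export
sirs_gillespie_cases <- function(grid, params, infections, t, n_runs,
                                 seed = 1L) {
  set.seed(seed)
  n <- grid$n_sites
  A <- as.matrix(grid$A)
  N <- grid$N
  beta <- params$beta; alpha <- params$alpha; gamma <- params$gamma
  lb <- params$lam * params$beta
  inf0 <- rep(infections, length.out = n)
  out <- matrix(0L, n_runs, n)
  for (run in seq_len(n_runs)) {
    i <- inf0; r <- integer(n); tt <- 0
    repeat {
      s <- N - i - r
      rate_inf <- (beta * i + lb * as.vector(A %*% i)) * pmax(s, 0)
      rate_rec <- alpha * i
      rate_wan <- gamma * r
      rts <- c(rate_inf, rate_rec, rate_wan)
      tot <- sum(rts)
      if (tot <= 0) break
      tt <- tt + stats::rexp(1L, tot)
      if (tt > t) break
      ev <- sample.int(3L * n, 1L, prob = rts)
      site <- (ev - 1L) %% n + 1L
      type <- (ev - 1L) %/% n + 1L
      if (type == 1L) i[site] <- i[site] + 1L
      else if (type == 2L) { i[site] <- i[site] - 1L; r[site] <- r[site] + 1L }
      else r[site] <- r[site] - 1L
    }
    out[run, ] <- i + r
  }
  attr(out, "seed") <- seed
  out
}
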