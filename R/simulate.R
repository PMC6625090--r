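#' Thomas cluster-process parameters
#'
#' Parameters of the Poisson cluster process used to emulate immunogold
#' nanocluster patterns: Poisson parents of intensity `kappa` (per nm^2),
#' Poisson(`mu`) offspring per parent, isotropic Gaussian offspring
#' displacement with standard deviation `sigma` (nm), and an independent
#' labeling (retention) probability modeling incomplete antibody labeling.
#' Defaults (`kappa = 5e-5`, i.e. 50 parents per um^2; `mu = 5`;
#' `sigma = 10` nm) give ~250 points per 1 um^2 sheet with cluster radii of
#' tens of nm, echoing realistic gold densities and peak clustering scales.
#'
#' @param kappa Parent intensity in nm^-2 (`> 0`).
#' @param mu Mean offspring per parent (`> 0`).
#' @param sigma Gaussian offspring dispersion in nm (`> 0`).
#' @param labeling_efficiency Retention fraction in (0, 1].
#' @return A `thomas_params` list.
#' @export
thomas_params <- function(kappa = 5e-5, mu = 5, sigma = 10,
                          labeling_efficiency = 1) {
  stopifnot(kappa > 0, mu > 0, sigma > 0,
            labeling_efficiency > 0, labeling_efficiency <= 1)
  structure(list(kappa = kappa, mu = mu, sigma = sigma,
                 labeling_efficiency = labeling_efficiency),
            class = "thomas_params")
}

#' Simulate complete spatial randomness (CSR)
#'
#' Places exactly `n` independent uniform points in the region -- the null
#' model of every clustering statistic in the package.
#'
#' @param n Number of points (`>= 0`).
#' @param region A [study_region()].
#' @param seed Integer seed.
#' @return A [point_pattern()].
#' @export
simulate_csr <- function(n, region = study_region(), seed = 1) {
  stopifnot(n >= 0)
  withr::with_seed(seed, {
    point_pattern(
      tibble::tibble(x = stats::runif(n, region$x_min, region$x_max),
                     y = stats::runif(n, region$y_min, region$y_max)),
      region = region, channel = "csr")
  })
}

#' Simulate a Thomas cluster process
#'
#' Parents are Poisson(`kappa * A`) uniform in the region expanded by a
#' `4 * sigma` guard band (so clusters seeded just outside the window still
#' contribute points, avoiding edge-truncation bias); each parent gets
#' Poisson(`mu`) offspring displaced by isotropic Gaussian(`sigma`);
#' offspring falling outside the region are discarded, and points are then
#' independently thinned at `labeling_efficiency`.
#'
#' @param params A [thomas_params()].
#' @param region A [study_region()].
#' @param seed Integer seed.
#' @return A [point_pattern()].
#' @export
simulate_thomas <- function(params = thomas_params(), region = study_region(),
                            seed = 1) {
  stopifnot(inherits(params, "thomas_params"))
  withr::with_seed(seed, {
    pts <- thomas_points(params, region)
    if (params$labeling_efficiency < 1) {
      keep <- stats::runif(nrow(pts)) <= params$labeling_efficiency
      pts <- pts[keep, , drop = FALSE]
    }
    point_pattern(pts, region = region, channel = "thomas")
  })
}

# offspring inside the closed region; runs inside a caller-managed seed
thomas_points <- function(params, region) {
  g <- 4 * params$sigma
  ax <- c(region$x_min - g, region$x_max + g)
  ay <- c(region$y_min - g, region$y_max + g)
  a_exp <- diff(ax) * diff(ay)
  n_par <- stats::rpois(1, params$kappa * a_exp)
  if (n_par == 0) {
    return(tibble::tibble(x = numeric(0), y = numeric(0)))
  }
  px <- stats::runif(n_par, ax[1], ax[2])
  py <- stats::runif(n_par, ay[1], ay[2])
  n_off <- stats::rpois(n_par, params$mu)
  ox <- rep(px, n_off) + stats::rnorm(sum(n_off), 0, params$sigma)
  oy <- rep(py, n_off) + stats::rnorm(sum(n_off), 0, params$sigma)
  keep <- points_in_region(ox, oy, region)
  tibble::tibble(x = ox[keep], y = oy[keep])
}

#' Closed-form K-function of the Thomas process
#'
#' `K(r) = pi r^2 + (1 - exp(-r^2 / (4 sigma^2))) / kappa` -- the analytic
#' oracle used to validate the simulator and to fit cluster parameters.
#' Labeling thinning leaves K unchanged.
#'
#' @param params A [thomas_params()].
#' @param r Radii in nm (`> 0`), vectorized.
#' @return K values in nm^2.
#' @examples
#' thomas_k_closed_form(thomas_params(), 20)  # ~13899 nm^2
#' @export
thomas_k_closed_form <- function(params, r) {
  stopifnot(inherits(params, "thomas_params"), all(r > 0))
  pi * r^2 + (1 - exp(-r^2 / (4 * params$sigma^2))) / params$kappa
}

#' Curvature-response mixture parameters
#'
#' Emulates the monomer/multimer population shifts seen when membrane
#' curvature modulates nanoclustering: a fraction `phi` of the particles is
#' placed as Thomas-cluster offspring and the remainder as CSR, so `phi`
#' tunes the clustered fraction from fully random (0) to fully clustered
#' (1) at a fixed total count.
#'
#' @param phi Clustered fraction in [0, 1].
#' @param base A [thomas_params()] supplying the cluster geometry.
#' @param n_total Particles per region (default 200).
#' @return A `curvature_params` list.
#' @export
curvature_params <- function(phi, base = thomas_params(), n_total = 200) {
  stopifnot(phi >= 0, phi <= 1, inherits(base, "thomas_params"), n_total >= 0)
  structure(list(phi = phi, base = base, n_total = as.integer(n_total)),
            class = "curvature_params")
}

#' Simulate a curvature-modulated clustering mixture
#'
#' Places `round(phi * n_total)` points as offspring of a shared Thomas
#' parent set (each point picks a uniform parent and a Gaussian(sigma)
#' offset, redrawn until it lands inside the region) and the remaining
#' points as CSR, for exactly `n_total` points.
#'
#' @param params A [curvature_params()].
#' @param region A [study_region()].
#' @param seed Integer seed.
#' @return A [point_pattern()].
#' @export
simulate_curvature_response <- function(params, region = study_region(),
                                        seed = 1) {
  stopifnot(inherits(params, "curvature_params"))
  base <- params$base
  withr::with_seed(seed, {
    n_cl <- round(params$phi * params$n_total)
    n_csr <- params$n_total - n_cl
    cl <- offspring_in_region(n_cl, base, region)
    cx <- stats::runif(n_csr, region$x_min, region$x_max)
    cy <- stats::runif(n_csr, region$y_min, region$y_max)
    point_pattern(tibble::tibble(x = c(cl$x, cx), y = c(cl$y, cy)),
                  region = region, channel = "curvature_mixture")
  })
}

# exactly n offspring of a fresh guard-banded parent set, rejected into the
# region; runs inside a caller-managed seed
offspring_in_region <- function(n, params, region, parents = NULL) {
  if (n == 0) {
    return(tibble::tibble(x = numeric(0), y = numeric(0)))
  }
  if (is.null(parents)) {
    g <- 4 * params$sigma
    ax <- c(region$x_min - g, region$x_max + g)
    ay <- c(region$y_min - g, region$y_max + g)
    n_par <- max(1L, stats::rpois(1, params$kappa * diff(ax) * diff(ay)))
    parents <- tibble::tibble(x = stats::runif(n_par, ax[1], ax[2]),
                              y = stats::runif(n_par, ay[1], ay[2]))
  }
  x <- numeric(0)
  y <- numeric(0)
  for (i in seq_len(1000)) {
    m <- n - length(x)
    if (m == 0) break
    pid <- sample.int(nrow(parents), m, replace = TRUE)
    nx <- parents$x[pid] + stats::rnorm(m, 0, params$sigma)
    ny <- parents$y[pid] + stats::rnorm(m, 0, params$sigma)
    keep <- points_in_region(nx, ny, region)
    x <- c(x, nx[keep])
    y <- c(y, ny[keep])
  }
  if (length(x) < n) {
    stop("offspring rejection sampling failed to fill the region", call. = FALSE)
  }
  tibble::tibble(x = x, y = y)
}

#' Simulate a two-channel gold pattern
#'
#' Generates paired big/small channels with controlled cross-channel
#' structure:
#' * `"colocalized"` -- both channels are offspring of one shared Thomas
#'   parent set, so their clusters coincide;
#' * `"independent"` -- each channel has its own independent parent set;
#' * `"segregated"` -- the big channel clusters around its parents while
#'   small-channel points are rejected within `3 * sigma` of any big
#'   parent, carving mutual exclusion zones.
#'
#' Channel counts are fixed at `n_b` / `n_s`.
#'
#' @param mode `"colocalized"`, `"independent"` or `"segregated"`.
#' @param params A [thomas_params()].
#' @param n_b,n_s Points per channel (`>= 1`).
#' @param region A [study_region()].
#' @param seed Integer seed.
#' @return A [bivariate_pattern()].
#' @export
simulate_bivariate <- function(mode = c("colocalized", "independent",
                                        "segregated"),
                               params = thomas_params(), n_b = 100, n_s = 100,
                               region = study_region(), seed = 1) {
  mode <- match.arg(mode)
  stopifnot(inherits(params, "thomas_params"), n_b >= 1, n_s >= 1)
  withr::with_seed(seed, {
    g <- 4 * params$sigma
    ax <- c(region$x_min - g, region$x_max + g)
    ay <- c(region$y_min - g, region$y_max + g)
    draw_parents <- function() {
      n_par <- max(1L, stats::rpois(1, params$kappa * diff(ax) * diff(ay)))
      tibble::tibble(x = stats::runif(n_par, ax[1], ax[2]),
                     y = stats::runif(n_par, ay[1], ay[2]))
    }
    par_b <- draw_parents()
    big <- offspring_in_region(n_b, params, region, parents = par_b)
    small <- switch(mode,
      colocalized = offspring_in_region(n_s, params, region, parents = par_b),
      independent = offspring_in_region(n_s, params, region,
                                        parents = draw_parents()),
      segregated = {
        excl <- 3 * params$sigma
        par_s <- draw_parents()
        x <- numeric(0); y <- numeric(0)
        for (i in seq_len(1000)) {
          m <- n_s - length(x)
          if (m == 0) break
          cand <- offspring_in_region(m, params, region, parents = par_s)
          d2 <- outer(cand$x, par_b$x, "-")^2 + outer(cand$y, par_b$y, "-")^2
          keep <- apply(d2, 1, min) > excl^2
          x <- c(x, cand$x[keep]); y <- c(y, cand$y[keep])
        }
        if (length(x) < n_s) {
          stop("segregated simulation: exclusion rejection failed", call. = FALSE)
        }
        tibble::tibble(x = x, y = y)
      })
    bivariate_pattern(
      point_pattern(big, region = region, channel = "big-6nm"),
      point_pattern(small, region = region, channel = "small-2nm"))
  })
}

#' Thin a pattern by incomplete labeling
#'
#' Retains each point independently with probability `efficiency`, modeling
#' incomplete antibody labeling. Independent thinning leaves the K-function
#' invariant in expectation, which is why clustering readouts are expected
#' to be robust to labeling density.
#'
#' @param pattern A [point_pattern()].
#' @param efficiency Retention probability in (0, 1].
#' @param seed Integer seed.
#' @return A thinned [point_pattern()].
#' @export
thin_by_labeling <- function(pattern, efficiency, seed = 1) {
  stopifnot(inherits(pattern, "point_pattern"),
            efficiency > 0, efficiency <= 1)
  if (efficiency == 1) {
    return(pattern)
  }
  withr::with_seed(seed, {
    keep <- stats::runif(pattern$n) <= efficiency
    point_pattern(pattern$points[keep, , drop = FALSE],
                  region = pattern$region, channel = pattern$channel)
  })
}

#' Fit Thomas cluster parameters to pooled empirical K
#'
#' Pools the empirical K-function over replicate images (pointwise mean)
#' and least-squares fits the closed form
#' `K(r) = pi r^2 + (1 - exp(-r^2 / (4 sigma^2))) / kappa` over
#' `r_range` (default 5--100 nm), estimating `kappa` and `sigma` by
#' Levenberg-Marquardt. Starting values come from the large-r plateau of
#' the clustering excess (`1/kappa`) and its half-saturation radius.
#'
#' @param patterns List of [point_pattern()]s (replicate images).
#' @param grid A [radius_grid()].
#' @param r_range Fit range in nm, default `c(5, 100)`.
#' @return A `thomas_fit` object; `tidy()` gives the estimates.
#' @export
fit_thomas <- function(patterns, grid = radius_grid(), r_range = c(5, 100)) {
  stopifnot(length(patterns) >= 1, length(r_range) == 2)
  grid <- radius_grid(grid)
  kmat <- vapply(patterns, function(p) k_function(p, grid)$k,
                 numeric(length(grid)))
  kbar <- rowMeans(kmat)
  sel <- grid >= r_range[1] & grid <= r_range[2]
  df <- data.frame(r = as.numeric(grid)[sel], k = kbar[sel])
  excess <- pmax(df$k - pi * df$r^2, 0)
  plateau <- max(mean(utils::tail(excess, 10)), 1e-8)
  kappa0 <- 1 / plateau
  half <- df$r[which(excess >= plateau * (1 - exp(-1)))[1]]
  sigma0 <- max(half / 2, 1, na.rm = TRUE)
  fit <- minpack.lm::nlsLM(
    k ~ pi * r^2 + (1 - exp(-r^2 / (4 * sigma^2))) / kappa,
    data = df, start = list(kappa = kappa0, sigma = sigma0),
    lower = c(kappa = 1e-10, sigma = 0.1),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  est <- stats::coef(fit)
  structure(
    list(kappa = unname(est["kappa"]), sigma = unname(est["sigma"]),
         fit = fit, n_images = length(patterns), r_range = r_range),
    class = "thomas_fit")
}

#' @export
print.thomas_fit <- function(x, ...) {
  cat(sprintf("<thomas_fit> kappa = %.3g nm^-2, sigma = %.3g nm (pooled over %d image(s))\n",
              x$kappa, x$sigma, x$n_images))
  invisible(x)
}

#' @export
tidy.thomas_fit <- function(x, ...) {
  tibble::tibble(term = c("kappa", "sigma"),
                 estimate = c(x$kappa, x$sigma))
}

#' @export
glance.thomas_fit <- function(x, ...) {
  tibble::tibble(kappa = x$kappa, sigma = x$sigma, n_images = x$n_images,
                 r_lo = x$r_range[1], r_hi = x$r_range[2])
}
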