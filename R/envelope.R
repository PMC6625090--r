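#' Monte-Carlo CSR confidence envelope for L(r) - r
#'
#' Simulates `n_sims` patterns of exactly `n` uniform points in the region
#' (CSR conditioned on the observed count), computes each `L(r) - r` curve,
#' and returns the pointwise `level`-quantile at every grid radius. Raw
#' curves are divided by this envelope ("standardized"), so a standardized
#' value of 1 marks the confidence limit: 99% is the univariate default.
#'
#' Quantiles use linear interpolation between order statistics
#' (`stats::quantile` type 7).
#'
#' @param n Number of points per null simulation (`>= 2`).
#' @param region A [study_region()].
#' @param grid A [radius_grid()].
#' @param level Envelope level in (0, 1); default `0.99`.
#' @param n_sims Number of simulations (`>= 100`; default 1000).
#' @param seed Integer seed; the envelope is reproducible given the seed.
#' @return An `mc_envelope`: tibble with columns `r` and `env`, with
#'   `level`, `n_sims`, `seed` and `n` attributes.
#' @export
csr_envelope <- function(n, region = study_region(), grid = radius_grid(),
                         level = 0.99, n_sims = 1000, seed = 1) {
  stopifnot(n >= 2, n_sims >= 100)
  if (level <= 0 || level >= 1) {
    stop("csr_envelope: `level` must lie in (0, 1)", call. = FALSE)
  }
  grid <- radius_grid(grid)
  lmat <- withr::with_seed(seed, {
    vapply(seq_len(n_sims), function(i) {
      x <- stats::runif(n, region$x_min, region$x_max)
      y <- stats::runif(n, region$y_min, region$y_max)
      sqrt(k_values(x, y, region, grid) / pi) - as.numeric(grid)
    }, numeric(length(grid)))
  })
  lmat <- matrix(lmat, nrow = length(grid))
  env <- apply(lmat, 1, stats::quantile, probs = level, names = FALSE, type = 7)
  new_envelope(grid, env, level = level, n_sims = n_sims, seed = seed, n = n)
}

new_envelope <- function(grid, env, level, n_sims, seed, n) {
  out <- tibble::tibble(r = as.numeric(grid), env = env)
  structure(out, class = c("mc_envelope", class(out)),
            level = level, n_sims = n_sims, seed = seed, n = n)
}

#' Standardize an L-curve against its Monte-Carlo envelope
#'
#' Divides `l_minus_r` pointwise by the envelope. Radii where the envelope
#' is at or below `tol` (which happens at tiny r, where most null curves sit
#' at `-r`) are flagged undefined and excluded from the peak: dividing by a
#' vanishing or negative quantile would blow up or flip signs. The peak of
#' the standardized curve is `Lmax`, the scalar nanoclustering summary;
#' values above 1 exceed the confidence limit.
#'
#' @param curve A `k_curve` (or tibble with `r` and `l_minus_r`).
#' @param envelope An `mc_envelope` on the same radius grid.
#' @param tol Envelope tolerance in nm below which standardization is
#'   undefined; default `1e-9`.
#' @return A `std_curve`: tibble with columns `r`, `std`, `defined`,
#'   carrying `l_max` and `r_at_max` attributes.
#' @export
standardize_curve <- function(curve, envelope, tol = 1e-9) {
  stopifnot(is.data.frame(curve),
            is.data.frame(envelope), all(c("r", "env") %in% names(envelope)))
  if (!"l_minus_r" %in% names(curve) && "l_biv_minus_r" %in% names(curve)) {
    curve$l_minus_r <- curve$l_biv_minus_r
  }
  stopifnot(all(c("r", "l_minus_r") %in% names(curve)))
  if (nrow(curve) != nrow(envelope) ||
      any(abs(curve$r - envelope$r) > 1e-9)) {
    stop("standardize_curve: curve and envelope radius grids differ",
         call. = FALSE)
  }
  defined <- envelope$env > tol
  std <- ifelse(defined, curve$l_minus_r / envelope$env, NA_real_)
  out <- tibble::tibble(r = curve$r, std = std, defined = defined)
  pk <- if (any(defined)) peak_of(out) else list(l_max = NA_real_, r = NA_real_)
  structure(out, class = c("std_curve", class(out)),
            l_max = pk$l_max, r_at_max = pk$r,
            level = attr(envelope, "level", exact = TRUE))
}

peak_of <- function(std_tbl) {
  ok <- which(std_tbl$defined)
  m <- max(std_tbl$std[ok])
  # ties broken toward the smallest radius
  list(l_max = m, r = std_tbl$r[ok[which(std_tbl$std[ok] == m)[1]]])
}

#' Peak of a standardized clustering curve (Lmax)
#'
#' Returns the maximum standardized `L(r) - r` value over the defined radii
#' and the smallest radius attaining it. `Lmax > 1` indicates statistically
#' meaningful nanoclustering (the curve exceeds its confidence envelope).
#'
#' @param std A `std_curve` from [standardize_curve()].
#' @return One-row tibble with columns `l_max` and `r_at_max`.
#' @export
lmax <- function(std) {
  stopifnot(is.data.frame(std), all(c("r", "std", "defined") %in% names(std)))
  if (!any(std$defined)) {
    stop("lmax: no defined radii in the standardized curve", call. = FALSE)
  }
  pk <- peak_of(std)
  tibble::tibble(l_max = pk$l_max, r_at_max = pk$r)
}

#' Per-image Lmax for a group of patterns
#'
#' Computes the standardized `Lmax` for each pattern in a replicate group
#' (one pattern per micrograph region). Envelopes are conditioned on each
#' pattern's observed point count and cached, so patterns sharing a count
#' share one envelope. The raw-curve peak (`l_max_raw`, before envelope
#' standardization) is reported as a secondary output.
#'
#' @param patterns List of [point_pattern()]s sharing region dimensions.
#' @param grid A [radius_grid()].
#' @param level Envelope level (default 0.99).
#' @param n_sims Envelope simulations per distinct count (default 1000).
#' @param seed Integer seed for the envelopes.
#' @return Tibble with one row per pattern: `image`, `n`, `l_max`,
#'   `r_at_max`, `l_max_raw`.
#' @export
group_lmax <- function(patterns, grid = radius_grid(), level = 0.99,
                       n_sims = 1000, seed = 1) {
  stopifnot(length(patterns) >= 1)
  ref <- patterns[[1]]$region
  ok <- vapply(patterns, function(p) region_equal(p$region, ref), logical(1))
  if (!all(ok)) {
    stop("group_lmax: all patterns must share the same region dimensions",
         call. = FALSE)
  }
  grid <- radius_grid(grid)
  env_cache <- new.env(parent = emptyenv())
  purrr::map_dfr(seq_along(patterns), function(i) {
    p <- patterns[[i]]
    key <- as.character(p$n)
    if (is.null(env_cache[[key]])) {
      env_cache[[key]] <- csr_envelope(p$n, ref, grid, level = level,
                                       n_sims = n_sims, seed = seed)
    }
    cv <- k_function(p, grid)
    sc <- standardize_curve(cv, env_cache[[key]])
    pk <- lmax(sc)
    tibble::tibble(image = i, n = p$n, l_max = pk$l_max,
                   r_at_max = pk$r_at_max, l_max_raw = max(cv$l_minus_r))
  })
}
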