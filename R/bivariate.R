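#' Bivariate Ripley K-function for two-channel gold patterns
#'
#' Estimates the cross K-functions between the big-gold and small-gold
#' channels,
#' `K_bs(r) = A / (n_b n_s) * sum_{i in big} sum_{j in small} w_ij 1(d_ij <= r)`
#' (edge weights at the big centers), `K_sb(r)` symmetrically with small
#' centers, and the combined estimator
#' `K_biv(r) = (n_b + n_s)^-1 [n_b K_sb(r) + n_s K_bs(r)]`,
#' transformed to `L_biv(r) - r = sqrt(K_biv / pi) - r`. Under independent
#' channels `K_biv(r)` has expectation `pi r^2`; values above indicate
#' co-clustering, values below spatial segregation.
#'
#' @param pair A [bivariate_pattern()] with at least one point per channel.
#' @param grid A [radius_grid()].
#' @return A `biv_k_curve`: tibble with columns `r`, `k_bs`, `k_sb`,
#'   `k_biv`, `l_biv_minus_r`, carrying `n_b`, `n_s` and the window area as
#'   attributes.
#' @export
bivariate_k <- function(pair, grid = radius_grid()) {
  stopifnot(inherits(pair, "bivariate_pattern"))
  if (pair$n_b < 1 || pair$n_s < 1) {
    stop("bivariate_k: both channels need at least one point", call. = FALSE)
  }
  grid <- radius_grid(grid)
  region <- pair$big$region
  ks <- biv_k_values(pair$big$points$x, pair$big$points$y,
                     pair$small$points$x, pair$small$points$y, region, grid)
  out <- tibble::tibble(
    r = as.numeric(grid), k_bs = ks$k_bs, k_sb = ks$k_sb, k_biv = ks$k_biv,
    l_biv_minus_r = sqrt(ks$k_biv / pi) - as.numeric(grid))
  structure(out, class = c("biv_k_curve", class(out)),
            n_b = pair$n_b, n_s = pair$n_s, area = region$area)
}

biv_k_values <- function(bx, by, sx, sy, region, grid) {
  nb <- length(bx)
  ns <- length(sx)
  grid <- as.numeric(grid)
  # cross distances: rows = big, cols = small; pairs beyond the largest
  # grid radius never enter the indicator, so skip their edge weights
  d <- sqrt(outer(bx, sx, "-")^2 + outer(by, sy, "-")^2)
  keep <- which(d <= max(grid))
  dv <- d[keep]
  if (length(dv) == 0) {
    z <- numeric(length(grid))
    return(list(k_bs = z, k_sb = z, k_biv = z))
  }
  bi <- row(d)[keep]
  si <- col(d)[keep]
  w_big <- edge_weights(bx[bi], by[bi], dv, region)
  w_small <- edge_weights(sx[si], sy[si], dv, region)
  o <- order(dv)
  ds <- dv[o]
  pos <- findInterval(grid, ds)
  cum_at <- function(w) {
    cw <- cumsum(w[o])
    ifelse(pos > 0, cw[pmax(pos, 1)], 0)
  }
  scale <- region$area / (nb * ns)
  k_bs <- scale * cum_at(w_big)
  k_sb <- scale * cum_at(w_small)
  list(k_bs = k_bs, k_sb = k_sb,
       k_biv = (nb * k_sb + ns * k_bs) / (nb + ns))
}

#' Monte-Carlo null envelope for the bivariate L-curve
#'
#' Builds the pointwise `level`-quantile (95% default) of `L_biv(r) - r`
#' under a null of no cross-channel association. The default null
#' (`"csr_small"`) holds the observed big-gold pattern fixed and redraws the
#' small channel as CSR with its observed count: this tests association
#' without assuming the big channel is itself unclustered. The alternative
#' `"toroidal"` null preserves both channels' internal clustering by
#' applying a random toroidal shift to the small channel.
#'
#' @param pair A [bivariate_pattern()].
#' @param grid A [radius_grid()].
#' @param level Envelope level; default `0.95`.
#' @param n_sims Number of null simulations (`>= 100`; default 1000).
#' @param seed Integer seed.
#' @param null `"csr_small"` (default) or `"toroidal"`.
#' @return An `mc_envelope` tibble (`r`, `env`).
#' @export
biv_null_envelope <- function(pair, grid = radius_grid(), level = 0.95,
                              n_sims = 1000, seed = 1,
                              null = c("csr_small", "toroidal")) {
  null <- match.arg(null)
  stopifnot(inherits(pair, "bivariate_pattern"), n_sims >= 100)
  if (level <= 0 || level >= 1) {
    stop("biv_null_envelope: `level` must lie in (0, 1)", call. = FALSE)
  }
  grid <- radius_grid(grid)
  lmat <- biv_null_curves(pair, grid, n_sims, seed, null)
  env <- apply(lmat, 1, stats::quantile, probs = level, names = FALSE, type = 7)
  new_envelope(grid, env, level = level, n_sims = n_sims, seed = seed,
               n = pair$n_s)
}

# matrix of null L_biv(r)-r curves, one column per simulation
biv_null_curves <- function(pair, grid, n_sims, seed, null) {
  region <- pair$big$region
  bx <- pair$big$points$x
  by <- pair$big$points$y
  ns <- pair$n_s
  withr::with_seed(seed, {
    vapply(seq_len(n_sims), function(i) {
      if (null == "csr_small") {
        sx <- stats::runif(ns, region$x_min, region$x_max)
        sy <- stats::runif(ns, region$y_min, region$y_max)
      } else {
        wd <- region$x_max - region$x_min
        ht <- region$y_max - region$y_min
        sx <- region$x_min + (pair$small$points$x - region$x_min +
                                stats::runif(1, 0, wd)) %% wd
        sy <- region$y_min + (pair$small$points$y - region$y_min +
                                stats::runif(1, 0, ht)) %% ht
      }
      ks <- biv_k_values(bx, by, sx, sy, region, grid)
      sqrt(ks$k_biv / pi) - as.numeric(grid)
    }, numeric(length(grid)))
  }) |>
    matrix(nrow = length(grid))
}

#' L-function bivariate integrated (LBI) co-localization index
#'
#' Integrates the standardized bivariate curve `Std L_biv(r) - r` over the
#' fixed 10--110 nm range by the trapezoidal rule on the 1-nm grid. A curve
#' held exactly at its 95% envelope integrates to 100, so LBI = 100 marks
#' the confidence limit; larger values indicate co-clustering and negative
#' values segregation (signs are preserved, nothing is truncated).
#'
#' @param std A `std_curve` of the bivariate L-curve (from
#'   [standardize_curve()] with a [biv_null_envelope()]).
#' @param r_lo,r_hi Integration limits in nm (defaults 10 and 110,
#'   inclusive).
#' @return One-row tibble with columns `lbi`, `r_lo`, `r_hi`.
#' @export
lbi <- function(std, r_lo = 10, r_hi = 110) {
  stopifnot(is.data.frame(std), all(c("r", "std", "defined") %in% names(std)),
            r_lo < r_hi)
  inside <- std$r >= r_lo & std$r <= r_hi
  if (!any(std$r == r_lo) || !any(std$r == r_hi)) {
    stop("lbi: the radius grid must contain both integration endpoints",
         call. = FALSE)
  }
  if (!all(std$defined[inside])) {
    bad <- std$r[inside & !std$defined]
    stop(sprintf("lbi: standardized curve undefined at radii %s nm inside [%g, %g]",
                 paste(utils::head(bad, 5), collapse = ", "), r_lo, r_hi),
         call. = FALSE)
  }
  r <- std$r[inside]
  v <- std$std[inside]
  tibble::tibble(lbi = trapz(r, v), r_lo = r_lo, r_hi = r_hi)
}

trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)

#' Monte-Carlo ranking significance for an observed LBI
#'
#' One-sided (co-clustering) rank p-value of the observed LBI against LBI
#' values from null simulations: `p = (1 + #{null >= observed}) / (1 + m)`.
#'
#' @param observed Observed LBI (a number, or the tibble from [lbi()]).
#' @param null_lbis Numeric vector of null LBI values (`>= 100` draws).
#' @return One-row tibble with `p_value`, `n_null`.
#' @export
lbi_significance <- function(observed, null_lbis) {
  if (is.data.frame(observed)) observed <- observed$lbi[1]
  if (length(null_lbis) < 100) {
    stop("lbi_significance: at least 100 null LBI values are required",
         call. = FALSE)
  }
  m <- length(null_lbis)
  tibble::tibble(p_value = (1 + sum(null_lbis >= observed)) / (1 + m),
                 n_null = m)
}

#' Full bivariate co-localization test for one image
#'
#' Convenience wrapper running the whole bivariate pipeline on one paired
#' pattern: cross K-curve, null envelope, standardization, LBI, and the
#' Monte-Carlo ranking p-value (null LBIs are computed from the same null
#' draws that define the envelope).
#'
#' @inheritParams biv_null_envelope
#' @param r_lo,r_hi LBI integration limits (nm).
#' @return A `lbi_test` object: list with `lbi` (one-row tibble including
#'   `p_value`), `std` (the standardized curve), `envelope`, `null_lbis`.
#' @export
lbi_test <- function(pair, grid = radius_grid(), level = 0.95, n_sims = 1000,
                     seed = 1, r_lo = 10, r_hi = 110,
                     null = c("csr_small", "toroidal")) {
  null <- match.arg(null)
  grid <- radius_grid(grid)
  lmat <- biv_null_curves(pair, grid, n_sims, seed, null)
  env_v <- apply(lmat, 1, stats::quantile, probs = level, names = FALSE,
                 type = 7)
  envelope <- new_envelope(grid, env_v, level = level, n_sims = n_sims,
                           seed = seed, n = pair$n_s)
  curve <- bivariate_k(pair, grid)
  names(curve)[names(curve) == "l_biv_minus_r"] <- "l_minus_r"
  std <- standardize_curve(curve, envelope)
  obs <- lbi(std, r_lo = r_lo, r_hi = r_hi)
  # standardize each null curve by the same envelope and integrate
  inside <- envelope$r >= r_lo & envelope$r <= r_hi
  defined <- envelope$env > 1e-9
  if (!all(defined[inside])) {
    stop("lbi_test: null envelope undefined inside the LBI range", call. = FALSE)
  }
  rr <- envelope$r[inside]
  null_lbis <- apply(lmat[inside, , drop = FALSE] / envelope$env[inside], 2,
                     function(v) trapz(rr, v))
  p <- lbi_significance(obs$lbi, null_lbis)
  structure(
    list(lbi = dplyr::bind_cols(obs, p), std = std, envelope = envelope,
         null_lbis = null_lbis),
    class = "lbi_test"
  )
}

#' @export
print.lbi_test <- function(x, ...) {
  cat(sprintf("<lbi_test> LBI = %.2f over [%g, %g] nm, p = %.4g (%d null draws)\n",
              x$lbi$lbi, x$lbi$r_lo, x$lbi$r_hi, x$lbi$p_value, x$lbi$n_null))
  invisible(x)
}

#' @export
tidy.lbi_test <- function(x, ...) x$lbi

#' @export
glance.lbi_test <- function(x, ...) {
  tibble::tibble(lbi = x$lbi$lbi, p_value = x$lbi$p_value,
                 n_null = x$lbi$n_null,
                 level = attr(x$envelope, "level", exact = TRUE))
}
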