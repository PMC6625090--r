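#' Univariate Ripley K-function with edge correction
#'
#' Estimates `K(r) = A * n^-2 * sum_{i != j} w_ij * 1(||x_i - x_j|| <= r)`
#' over the radius grid, where `A` is the window area, the sum runs over
#' ordered pairs, the indicator is inclusive, and `w_ij` is the rectangular
#' edge-correction weight for the circle centered at `x_i` with radius
#' `||x_i - x_j||` (see [edge_correction_weight()]). Under complete spatial
#' randomness (CSR) `K(r)` has expectation `pi * r^2`; values above that
#' indicate clustering at length scale `r`.
#'
#' @param pattern A [point_pattern()] with at least 2 points.
#' @param grid A [radius_grid()]; defaults to 1--240 nm in 1-nm steps.
#' @return A `k_curve`: a tibble with columns `r` (nm), `k` (nm^2) and
#'   `l_minus_r` (nm), carrying the pattern's `n` and window area as
#'   attributes.
#' @examples
#' pp <- point_pattern(data.frame(x = c(500, 500), y = c(490, 510)))
#' k_function(pp, radius_grid(c(10, 25)))
#' @export
k_function <- function(pattern, grid = radius_grid()) {
  stopifnot(inherits(pattern, "point_pattern"))
  if (pattern$n < 2) {
    stop("k_function: at least 2 points are required", call. = FALSE)
  }
  grid <- radius_grid(grid)
  k <- k_values(pattern$points$x, pattern$points$y, pattern$region, grid)
  new_k_curve(grid, k, n = pattern$n, area = pattern$region$area,
              channel = pattern$channel)
}

new_k_curve <- function(grid, k, n, area, channel = "") {
  out <- tibble::tibble(r = as.numeric(grid), k = k,
                        l_minus_r = sqrt(k / pi) - as.numeric(grid))
  structure(out, class = c("k_curve", class(out)),
            n = n, area = area, channel = channel)
}

# Fast path shared by all estimators and Monte-Carlo loops: K at each grid
# radius from the edge-weighted ordered-pair counts, via one sort + cumsum.
k_values <- function(x, y, region, grid) {
  n <- length(x)
  grid <- as.numeric(grid)
  dm <- as.matrix(stats::dist(cbind(x, y)))
  # pairs beyond the largest grid radius never enter the indicator, so
  # their (potentially ill-defined) edge weights are never needed
  keep <- row(dm) != col(dm) & dm <= max(grid)
  d <- dm[keep]
  if (length(d) == 0) {
    return(numeric(length(grid)))
  }
  w <- edge_weights(x[row(dm)[keep]], y[row(dm)[keep]], d, region)
  o <- order(d)
  cw <- cumsum(w[o])
  pos <- findInterval(grid, d[o])
  k <- ifelse(pos > 0, cw[pmax(pos, 1)], 0)
  region$area / n^2 * k
}

#' Linear L-transform of a K-curve
#'
#' Applies `L(r) - r = sqrt(K(r) / pi) - r`, the variance-stabilized
#' linearization of the K-function: 0 under CSR, positive for clustering,
#' negative for dispersion.
#'
#' @param curve A `k_curve` from [k_function()] (or any tibble with columns
#'   `r` and `k`).
#' @return The curve with its `l_minus_r` column (re)computed.
#' @export
l_curve <- function(curve) {
  stopifnot(is.data.frame(curve), all(c("r", "k") %in% names(curve)))
  if (any(curve$k < 0)) {
    stop("l_curve: negative K values are not admissible", call. = FALSE)
  }
  curve$l_minus_r <- sqrt(curve$k / pi) - curve$r
  curve
}
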