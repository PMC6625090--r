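#' Isotropic edge-correction weight in a rectangular window
#'
#' For a circle of radius `r` centered at a point inside the study region,
#' returns `w = 1 / p` where `p` is the fraction of the circle's
#' circumference lying inside the region. Pair counts in the K-function are
#' weighted by `w` so that neighbors lost beyond the window boundary are
#' compensated. `w = 1` for a fully interior circle, 2 on an edge, 4 on a
#' corner (for small `r`).
#'
#' The closed-form boundary-arc fraction for a rectangle is used (one-edge,
#' two-adjacent-edge and corner-overlap cases); if the circle exits through
#' two opposite edges the fraction is obtained by numerical arc integration
#' (4096 circumference samples).
#'
#' @param center Numeric length-2 `(x, y)` in nm; must lie inside the region.
#' @param r Circle radius in nm, `> 0`.
#' @param region A [study_region()].
#' @return Weight `>= 1`.
#' @examples
#' edge_correction_weight(c(500, 500), 100, study_region())  # 1
#' edge_correction_weight(c(0, 500), 5, study_region())      # 2
#' edge_correction_weight(c(0, 0), 5, study_region())        # 4
#' @export
edge_correction_weight <- function(center, r, region = study_region()) {
  stopifnot(length(center) == 2, is.numeric(center), r > 0)
  if (!points_in_region(center[1], center[2], region)) {
    stop("edge_correction_weight: center lies outside the study region",
         call. = FALSE)
  }
  edge_weights(center[1], center[2], r, region)
}

# Vectorized rectangle edge weights over (cx, cy, r) triples of equal length.
# Closed form: outside angle = sum of per-edge arcs 2*acos(d/r) minus the
# corner overlaps (pi/2 - asin(di/r) - asin(dj/r)) where the circle crosses
# two adjacent edges with di^2 + dj^2 < r^2.
edge_weights <- function(cx, cy, r, region) {
  n <- max(length(cx), length(cy), length(r))
  cx <- rep_len(cx, n); cy <- rep_len(cy, n); r <- rep_len(r, n)
  d1 <- cx - region$x_min
  d2 <- region$x_max - cx
  d3 <- cy - region$y_min
  d4 <- region$y_max - cy

  opp <- (d1 < r & d2 < r) | (d3 < r & d4 < r)

  arc <- function(d) ifelse(d < r, 2 * acos(pmin(d / r, 1)), 0)
  corner <- function(di, dj) {
    hit <- di < r & dj < r & (di^2 + dj^2 < r^2)
    ifelse(hit, pi / 2 - asin(pmin(di / r, 1)) - asin(pmin(dj / r, 1)), 0)
  }

  out <- arc(d1) + arc(d2) + arc(d3) + arc(d4) -
    corner(d1, d3) - corner(d1, d4) - corner(d2, d3) - corner(d2, d4)
  frac <- 1 - out / (2 * pi)

  if (any(opp)) {
    idx <- which(opp)
    frac[idx] <- vapply(idx, function(i) {
      arc_fraction_numeric(cx[i], cy[i], r[i], region)
    }, numeric(1))
  }
  if (any(frac <= 0)) {
    stop("edge correction undefined: circle circumference entirely outside the region",
         call. = FALSE)
  }
  1 / frac
}

arc_fraction_numeric <- function(cx, cy, r, region, n_samples = 4096L) {
  theta <- (seq_len(n_samples) - 0.5) * (2 * pi / n_samples)
  mean(points_in_region(cx + r * cos(theta), cy + r * sin(theta), region))
}
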