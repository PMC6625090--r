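#' Rectangular study region
#'
#' Defines the rectangular observation window (in nm) within which gold
#' coordinates are analyzed. The default matches a 1 um^2 plasma-membrane
#' sheet (1000 x 1000 nm), the window used throughout the EM pipeline.
#'
#' @param x_min,y_min,x_max,y_max Window boundaries in nm.
#' @return A `study_region` object with an `area` field (nm^2).
#' @examples
#' study_region()           # 1 um^2 default
#' study_region(0, 0, 500, 2000)
#' @export
study_region <- function(x_min = 0, y_min = 0, x_max = 1000, y_max = 1000) {
  stopifnot(is.numeric(x_min), is.numeric(y_min),
            is.numeric(x_max), is.numeric(y_max))
  if (!(x_max > x_min) || !(y_max > y_min)) {
    stop("study_region: x_max must exceed x_min and y_max must exceed y_min",
         call. = FALSE)
  }
  structure(
    list(x_min = as.numeric(x_min), y_min = as.numeric(y_min),
         x_max = as.numeric(x_max), y_max = as.numeric(y_max),
         area = (x_max - x_min) * (y_max - y_min)),
    class = "study_region"
  )
}

#' @export
print.study_region <- function(x, ...) {
  cat(sprintf("<study_region> [%g, %g] x [%g, %g] nm (area %g nm^2)\n",
              x$x_min, x$x_max, x$y_min, x$y_max, x$area))
  invisible(x)
}

region_equal <- function(a, b, tol = 1e-9) {
  all(abs(c(a$x_min - b$x_min, a$x_max - b$x_max,
            a$y_min - b$y_min, a$y_max - b$y_max)) <= tol)
}

# closed region: boundary points count as inside
points_in_region <- function(x, y, region) {
  x >= region$x_min & x <= region$x_max &
    y >= region$y_min & y <= region$y_max
}

#' Spatial point pattern of gold-particle coordinates
#'
#' Wraps a table of particle coordinates (nm) together with its study region
#' and an optional channel label. All coordinates must lie inside or on the
#' boundary of the region (the window is closed, so digitized edge particles
#' are retained).
#'
#' @param points A data frame with numeric columns `x` and `y` (nm), or a
#'   two-column numeric matrix.
#' @param region A [study_region()].
#' @param channel Free-text channel label (e.g., `"GFP-6nm"`).
#' @return A `point_pattern` with fields `points` (tibble), `region`,
#'   `channel`, and `n`.
#' @examples
#' pp <- point_pattern(data.frame(x = c(100, 300), y = c(200, 400)))
#' pp$n
#' @export
point_pattern <- function(points, region = study_region(), channel = "") {
  if (is.matrix(points)) {
    points <- as.data.frame(points)
    names(points) <- c("x", "y")
  }
  if (!all(c("x", "y") %in% names(points))) {
    stop("point_pattern: `points` must have columns x and y", call. = FALSE)
  }
  if (!inherits(region, "study_region")) {
    stop("point_pattern: `region` must be a study_region", call. = FALSE)
  }
  pts <- tibble::tibble(x = as.numeric(points$x), y = as.numeric(points$y))
  if (anyNA(pts$x) || anyNA(pts$y)) {
    stop("point_pattern: coordinates contain missing/non-numeric values",
         call. = FALSE)
  }
  inside <- points_in_region(pts$x, pts$y, region)
  if (!all(inside)) {
    bad <- which(!inside)
    stop(sprintf(
      "point_pattern: %d point(s) outside the study region (first offending row: %d at x=%g, y=%g)",
      length(bad), bad[1], pts$x[bad[1]], pts$y[bad[1]]), call. = FALSE)
  }
  structure(
    list(points = pts, region = region, channel = channel, n = nrow(pts)),
    class = "point_pattern"
  )
}

#' @export
print.point_pattern <- function(x, ...) {
  cat(sprintf("<point_pattern> %d point(s)%s in [%g, %g] x [%g, %g] nm\n",
              x$n, if (nzchar(x$channel)) paste0(" [", x$channel, "]") else "",
              x$region$x_min, x$region$x_max, x$region$y_min, x$region$y_max))
  invisible(x)
}

#' Paired two-channel point pattern
#'
#' Couples the big-gold (6-nm, GFP) and small-gold (2-nm, RFP) patterns
#' observed on one membrane sheet for bivariate co-localization analysis.
#' Both channels must share the same study region.
#'
#' @param big,small [point_pattern()] objects on the same region.
#' @return A `bivariate_pattern` with fields `big`, `small`, `n_b`, `n_s`.
#' @export
bivariate_pattern <- function(big, small) {
  stopifnot(inherits(big, "point_pattern"), inherits(small, "point_pattern"))
  if (!region_equal(big$region, small$region)) {
    stop("bivariate_pattern: big and small channels must share one study region",
         call. = FALSE)
  }
  structure(
    list(big = big, small = small, n_b = big$n, n_s = small$n),
    class = "bivariate_pattern"
  )
}

#' @export
print.bivariate_pattern <- function(x, ...) {
  cat(sprintf("<bivariate_pattern> big n_b = %d, small n_s = %d\n",
              x$n_b, x$n_s))
  invisible(x)
}

#' Radius grid for K-function evaluation
#'
#' The default grid is 1, 2, ..., 240 nm in 1-nm increments, the length-scale
#' range over which nanoclustering curves are evaluated.
#'
#' @param radii Strictly increasing positive radii in nm.
#' @return A numeric vector of class `radius_grid`.
#' @export
radius_grid <- function(radii = seq(1, 240, by = 1)) {
  radii <- as.numeric(radii)
  if (length(radii) < 1 || any(radii <= 0) || any(diff(radii) <= 0)) {
    stop("radius_grid: radii must be positive and strictly increasing",
         call. = FALSE)
  }
  structure(radii, class = c("radius_grid", "numeric"))
}
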