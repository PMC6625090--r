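#' RMS surface roughness of a topography map
#'
#' `R_q`, the root-mean-square average of the height deviation from the
#' mean image data plane: heights are leveled (mean subtraction by default,
#' or best-fit plane removal with `leveling = "plane"`) and the RMS of the
#' residuals returned, in the height units of the map (nm for AFM scans).
#'
#' @param heights Numeric matrix of heights (at least 2 x 2).
#' @param leveling `"mean"` (default) or `"plane"`.
#' @return R_q (scalar, same units as `heights`).
#' @examples
#' rq_roughness(matrix(c(1, -1, 1, -1), 2))  # 1
#' @export
rq_roughness <- function(heights, leveling = c("mean", "plane")) {
  leveling <- match.arg(leveling)
  stopifnot(is.matrix(heights), is.numeric(heights),
            nrow(heights) >= 2, ncol(heights) >= 2, all(is.finite(heights)))
  dev <- if (leveling == "mean") {
    heights - mean(heights)
  } else {
    d <- data.frame(z = as.vector(heights),
                    x = as.vector(col(heights)),
                    y = as.vector(row(heights)))
    matrix(stats::residuals(stats::lm(z ~ x + y, data = d)),
           nrow(heights), ncol(heights))
  }
  sqrt(mean(dev^2))
}

#' Donor-lifetime FRET efficiency
#'
#' `E = 1 - tau_DA / tau_D`, the standard donor-lifetime form: the
#' fractional shortening of the donor fluorescence lifetime in the presence
#' of the acceptor. Rows where `tau_donor_acceptor > tau_donor_only`
#' (unphysical for true FRET, but possible with measurement noise) produce
#' a warning, not an error, and a negative efficiency.
#'
#' @param measurements Data frame with numeric columns `tau_donor_only` and
#'   `tau_donor_acceptor` (ns); all lifetimes must be positive. Extra
#'   columns (e.g. the osmolality condition) are carried through.
#' @return The input as a tibble with an `efficiency` column appended.
#' @export
fret_efficiency <- function(measurements) {
  stopifnot(is.data.frame(measurements),
            all(c("tau_donor_only", "tau_donor_acceptor") %in%
                  names(measurements)))
  td <- measurements$tau_donor_only
  ta <- measurements$tau_donor_acceptor
  if (any(td <= 0) || any(ta <= 0)) {
    stop("fret_efficiency: lifetimes must be positive", call. = FALSE)
  }
  if (any(ta > td)) {
    warning(sprintf(
      "fret_efficiency: %d measurement(s) have tau_DA > tau_D (negative efficiency)",
      sum(ta > td)), call. = FALSE)
  }
  dplyr::mutate(tibble::as_tibble(measurements), efficiency = 1 - ta / td)
}

#' Nanobar geometry
#'
#' Geometry of one nanobar in an intensity image: a 2-um-long bar of width
#' 250 nm whose two ends are half circles of 125-nm radius (the end radius
#' is always `width / 2`). `center` and `angle` place the bar in the image;
#' `pixel_size` converts pixels to nm.
#'
#' @param length,width Bar dimensions in nm (length must exceed width).
#' @param center Bar center `(x, y)` in pixels (image column, row).
#' @param angle Bar axis angle in degrees (0 = horizontal).
#' @param pixel_size nm per pixel.
#' @return A `nanobar_geometry` list (with derived `end_radius`).
#' @export
nanobar_geometry <- function(length = 2000, width = 250, center,
                             angle = 0, pixel_size = 62) {
  stopifnot(length > width, width > 0, pixel_size > 0,
            is.numeric(center), base::length(center) == 2)
  structure(list(length = length, width = width, end_radius = width / 2,
                 center = as.numeric(center), angle = angle,
                 pixel_size = pixel_size),
            class = "nanobar_geometry")
}

# pixel-center coordinates rotated into the bar frame (u along the axis,
# v transverse), in nm
bar_frame <- function(image, geometry) {
  px <- (col(image) - geometry$center[1]) * geometry$pixel_size
  py <- (row(image) - geometry$center[2]) * geometry$pixel_size
  th <- -geometry$angle * pi / 180
  list(u = px * cos(th) - py * sin(th),
       v = px * sin(th) + py * cos(th))
}

nanobar_masks <- function(image, geometry) {
  f <- bar_frame(image, geometry)
  R <- geometry$end_radius
  half_len <- geometry$length / 2
  cap_u <- half_len - R
  ends <- abs(f$u) > cap_u &
    (abs(f$u) - cap_u)^2 + f$v^2 <= R^2
  # central axial rectangle with area equal to the two caps combined
  # (pi R^2), so end and center means are computed over equal areas
  center <- abs(f$u) <= pi * R / 4 & abs(f$v) <= R
  list(ends = ends, center = center)
}

#' Nanobar end/center fluorescence intensity ratio
#'
#' Quantifies curvature-preferential membrane binding on one nanobar: the
#' end region is the two half-disc caps at the bar tips (radius
#' `end_radius`), the center region is the axial central rectangle whose
#' area equals the combined cap area, and the ratio of their mean
#' intensities is returned. A ratio above 1 means enrichment at the curved
#' ends. The image should already be background-subtracted (see
#' [subtract_background()]) and the bar fully inside the image.
#'
#' @param image Numeric intensity matrix.
#' @param geometry A [nanobar_geometry()].
#' @return One-row tibble: `ratio`, `end_mean`, `center_mean`, `end_px`,
#'   `center_px`.
#' @export
nanobar_end_center_ratio <- function(image, geometry) {
  stopifnot(is.matrix(image), is.numeric(image),
            inherits(geometry, "nanobar_geometry"))
  m <- nanobar_masks(image, geometry)
  if (!any(m$ends) || !any(m$center)) {
    stop("nanobar_end_center_ratio: nanobar regions fall outside the image",
         call. = FALSE)
  }
  end_mean <- mean(image[m$ends])
  center_mean <- mean(image[m$center])
  if (center_mean <= 0) {
    stop("nanobar_end_center_ratio: non-positive mean center intensity, ratio undefined",
         call. = FALSE)
  }
  tibble::tibble(ratio = end_mean / center_mean, end_mean = end_mean,
                 center_mean = center_mean,
                 end_px = sum(m$ends), center_px = sum(m$center))
}

#' Averaged nanobar heat map
#'
#' Pixelwise mean of aligned nanobar sub-images (each already rotated to
#' the canonical horizontal orientation), producing the averaged
#' fluorescence intensity heat map over all imaged bars.
#'
#' @param images List of equal-sized numeric matrices (`>= 1`).
#' @return A numeric matrix, the mean image.
#' @export
nanobar_heatmap <- function(images) {
  stopifnot(is.list(images), length(images) >= 1)
  dims <- vapply(images, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("nanobar_heatmap: all sub-images must share the same dimensions",
         call. = FALSE)
  }
  Reduce(`+`, images) / length(images)
}

#' Rolling-ball style background subtraction
#'
#' Estimates the image background by grayscale morphological opening with a
#' disc structuring element of the given radius (the 2-D analogue of the
#' rolling-ball algorithm) and subtracts it, clamping at zero. Features
#' smaller than the disc survive the subtraction; a flat background maps to
#' zero, and the operation is idempotent on flat-background images.
#'
#' @param image Numeric intensity matrix.
#' @param radius Disc radius in pixels (default 3).
#' @return Background-subtracted matrix (`>= 0`).
#' @export
subtract_background <- function(image, radius = 3) {
  stopifnot(is.matrix(image), is.numeric(image), radius >= 1)
  lo <- min(image)
  hi <- max(image)
  if (hi == lo) {
    return(matrix(0, nrow(image), ncol(image)))
  }
  brush <- EBImage::makeBrush(2 * as.integer(radius) + 1, shape = "disc")
  # grayscale morphology operates on [0, 1] intensities; opening commutes
  # with increasing affine maps, so rescale in and out exactly
  bg01 <- EBImage::opening((image - lo) / (hi - lo), brush)
  bg <- bg01 * (hi - lo) + lo
  pmax(image - bg, 0)
}

#' SPR binding-isotherm table
#'
#' Assembles surface-plasmon-resonance binding isotherms: for each record
#' the protein association response is normalized by the lipid deposition
#' response (`ratio = ru_solute / ru_lipid`), and records are ordered by
#' concentration within each vesicle-diameter group, ready for plotting as
#' binding curves.
#'
#' @param records Data frame with numeric columns `ru_solute`, `ru_lipid`
#'   (`> 0`), `concentration` (uM) and `vesicle_diameter` (nm).
#' @return Tibble sorted by `vesicle_diameter`, then `concentration`, with
#'   a `ratio` column appended.
#' @export
spr_binding_table <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("ru_solute", "ru_lipid", "concentration",
                  "vesicle_diameter") %in% names(records)))
  if (any(records$ru_lipid <= 0)) {
    stop("spr_binding_table: ru_lipid must be positive", call. = FALSE)
  }
  records |>
    tibble::as_tibble() |>
    dplyr::mutate(ratio = .data$ru_solute / .data$ru_lipid) |>
    dplyr::arrange(.data$vesicle_diameter, .data$concentration)
}
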