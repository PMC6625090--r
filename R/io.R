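#' Read a gold-coordinate table into a point pattern
#'
#' Reads a delimited coordinate table (CSV or TSV) with two numeric
#' coordinate columns -- `x`/`y` in nm or ImageJ-style `X`/`Y` in pixels --
#' and converts to nm via `pixel_size`. Coordinates are continuous with the
#' origin at the region's lower-left corner.
#'
#' @param path Path to a CSV/TSV file.
#' @param pixel_size nm per pixel (`1` when the table is already in nm).
#' @param region A [study_region()]; converted points must fall inside it.
#' @param channel Channel label stored on the pattern.
#' @return A [point_pattern()].
#' @export
read_point_table <- function(path, pixel_size = 1, region = study_region(),
                             channel = "") {
  stopifnot(is.numeric(pixel_size), pixel_size > 0)
  delim <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  tab <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  nm <- tolower(names(tab))
  xi <- match("x", nm)
  yi <- match("y", nm)
  if (is.na(xi) || is.na(yi)) {
    stop(sprintf("read_point_table: '%s' must contain coordinate columns x,y (or X,Y)",
                 path), call. = FALSE)
  }
  xs <- suppressWarnings(as.numeric(tab[[xi]]))
  ys <- suppressWarnings(as.numeric(tab[[yi]]))
  if (nrow(tab) > 0 && (anyNA(xs) || anyNA(ys))) {
    stop(sprintf("read_point_table: non-numeric coordinate values in '%s' (first bad row: %d)",
                 path, which(is.na(xs) | is.na(ys))[1]), call. = FALSE)
  }
  pts <- tibble::tibble(x = xs * pixel_size, y = ys * pixel_size)
  inside <- points_in_region(pts$x, pts$y, region)
  if (!all(inside)) {
    bad <- which(!inside)[1]
    stop(sprintf(
      "read_point_table: row %d of '%s' converts to (%g, %g) nm, outside the study region",
      bad, path, pts$x[bad], pts$y[bad]), call. = FALSE)
  }
  point_pattern(pts, region = region, channel = channel)
}

#' Write an analysis-results table
#'
#' Writes a homogeneous results table as CSV at full numeric precision, so a
#' read-back reproduces the stored values exactly.
#'
#' @param records A non-empty data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(records, path) {
  if (!is.data.frame(records) || nrow(records) == 0) {
    stop("write_results_table: `records` must be a data frame with at least one row",
         call. = FALSE)
  }
  readr::write_csv(records, path, progress = FALSE)
  invisible(path)
}
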