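#' Oligomer population classification by proximity linkage
#'
#' Partitions gold particles into connected components of the graph linking
#' every pair within `threshold` nm (single linkage: pairwise links chain,
#' so a 0--10--20 nm chain at threshold 15 is one trimer). Components are
#' mapped to size classes -- monomer (1), dimer (2), trimer (3), multimer
#' (>= 4) -- giving the population distribution of clustered particles. The
#' 15-nm default is the proximity threshold used for immunogold population
#' analysis.
#'
#' Complete linkage (every pair in a component within `threshold`) is
#' available via `linkage = "complete"`.
#'
#' @param pattern A [point_pattern()] with at least one point.
#' @param threshold Linkage distance in nm (default 15).
#' @param linkage `"single"` (default) or `"complete"`.
#' @return An `oligomer_distribution`: tibble with one row per class and
#'   columns `class`, `components`, `particles`, `particle_fraction`,
#'   `component_fraction`; the vector of component sizes is attached as the
#'   `cluster_sizes` attribute.
#' @examples
#' pp <- point_pattern(data.frame(x = c(0, 10, 40, 100), y = 0),
#'                     study_region(0, 0, 200, 200))
#' classify_oligomers(pp)   # 1 dimer + 2 monomers
#' @export
classify_oligomers <- function(pattern, threshold = 15,
                               linkage = c("single", "complete")) {
  linkage <- match.arg(linkage)
  stopifnot(inherits(pattern, "point_pattern"), threshold > 0)
  if (pattern$n == 0) {
    stop("classify_oligomers: empty pattern", call. = FALSE)
  }
  sizes <- if (pattern$n == 1) {
    1L
  } else {
    hc <- stats::hclust(stats::dist(cbind(pattern$points$x, pattern$points$y)),
                        method = linkage)
    # cutree(h = threshold) merges all joins at height <= threshold,
    # i.e. the linkage is inclusive of pairs at exactly the threshold
    as.integer(tabulate(stats::cutree(hc, h = threshold)))
  }
  classes <- c("monomer", "dimer", "trimer", "multimer")
  bin <- pmin(sizes, 4L)
  comp <- vapply(1:4, function(k) sum(bin == k), integer(1))
  part <- vapply(1:4, function(k) sum(sizes[bin == k]), integer(1))
  out <- tibble::tibble(
    class = factor(classes, levels = classes),
    components = comp,
    particles = part,
    particle_fraction = part / pattern$n,
    component_fraction = comp / length(sizes))
  structure(out, class = c("oligomer_distribution", class(out)),
            cluster_sizes = sizes, threshold = threshold, linkage = linkage)
}
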