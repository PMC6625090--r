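#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
autoplot.k_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$r, y = .data$l_minus_r)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "r (nm)", y = "L(r) - r") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.std_curve <- function(object, ...) {
  ggplot2::ggplot(dplyr::filter(object, .data$defined),
                  ggplot2::aes(x = .data$r, y = .data$std)) +
    ggplot2::geom_hline(yintercept = 1, colour = "darkgreen") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "r (nm)", y = "Std L(r) - r",
                  caption = "green line: confidence-envelope level (1)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.mc_envelope <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$r, y = .data$env)) +
    ggplot2::geom_line(colour = "darkgreen") +
    ggplot2::labs(x = "r (nm)",
                  y = sprintf("%g%% envelope of L(r) - r (nm)",
                              100 * attr(object, "level", exact = TRUE))) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.oligomer_distribution <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$class,
                               y = .data$particle_fraction)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "fraction of particles") +
    ggplot2::theme_minimal()
}

#' Per-condition Lmax bar chart with SEM
#'
#' @param summary_tbl Tibble with `condition`, `mean_lmax`, `sem_lmax`
#'   (from [run_group_analysis()] or [summarize_group()]).
#' @return A ggplot object; the green line at 1 marks the 99% CI.
#' @export
plot_lmax_summary <- function(summary_tbl) {
  ggplot2::ggplot(summary_tbl,
                  ggplot2::aes(x = .data$condition, y = .data$mean_lmax)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_lmax - .data$sem_lmax,
                   ymax = .data$mean_lmax + .data$sem_lmax), width = 0.2) +
    ggplot2::geom_hline(yintercept = 1, colour = "darkgreen") +
    ggplot2::labs(x = NULL, y = "Lmax (mean +/- SEM)",
                  caption = "green line: 99% CI (standardized value 1)") +
    ggplot2::theme_minimal()
}

#' Per-condition LBI bar chart with SEM
#'
#' @param summary_tbl Tibble with `condition`, `mean_lbi`, `sem_lbi`.
#' @return A ggplot object; the green line at 100 marks the 95% CI.
#' @export
plot_lbi_summary <- function(summary_tbl) {
  ggplot2::ggplot(summary_tbl,
                  ggplot2::aes(x = .data$condition, y = .data$mean_lbi)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_lbi - .data$sem_lbi,
                   ymax = .data$mean_lbi + .data$sem_lbi), width = 0.2) +
    ggplot2::geom_hline(yintercept = 100, colour = "darkgreen") +
    ggplot2::labs(x = NULL, y = "LBI (mean +/- SEM)",
                  caption = "green line: 95% CI (LBI = 100)") +
    ggplot2::theme_minimal()
}

#' Render the standard report figures for an analysis bundle
#'
#' Produces the figures mirroring the standard presentation of the
#' pipeline's outputs: per-condition standardized-curve or raw L(r) - r
#' curve panels, the Lmax (or LBI) bar chart with SEM and its CI reference
#' line, and oligomer population histograms. Figures are returned as a
#' named list of ggplot objects and, when `out_dir` is given, also written
#' as PDFs.
#'
#' @param bundle A `nanoclust_bundle` from [run_group_analysis()].
#' @param out_dir Optional directory for PDF output.
#' @return Named list of ggplot objects, invisibly when writing files.
#' @export
render_report <- function(bundle, out_dir = NULL) {
  stopifnot(inherits(bundle, "nanoclust_bundle"))
  plots <- list()
  if (bundle$analysis == "univariate") {
    if (nrow(bundle$curves) == 0) {
      stop("render_report: empty bundle", call. = FALSE)
    }
    plots$curves <- ggplot2::ggplot(
      bundle$curves,
      ggplot2::aes(x = .data$r, y = .data$l_minus_r,
                   group = .data$image)) +
      ggplot2::geom_line(alpha = 0.4) +
      ggplot2::facet_wrap(ggplot2::vars(.data$condition)) +
      ggplot2::labs(x = "r (nm)", y = "L(r) - r") +
      ggplot2::theme_minimal()
    plots$lmax <- plot_lmax_summary(bundle$summary)
    plots$oligomers <- ggplot2::ggplot(
      bundle$oligomers,
      ggplot2::aes(x = .data$class, y = .data$particle_fraction)) +
      ggplot2::stat_summary(fun = mean, geom = "col", fill = "steelblue") +
      ggplot2::facet_wrap(ggplot2::vars(.data$condition)) +
      ggplot2::labs(x = NULL, y = "mean fraction of particles") +
      ggplot2::theme_minimal()
  } else {
    if (nrow(bundle$lbi) == 0) {
      stop("render_report: empty bundle", call. = FALSE)
    }
    plots$lbi <- plot_lbi_summary(bundle$summary)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(plots)) {
      ggplot2::ggsave(file.path(out_dir, paste0(nm, ".pdf")), plots[[nm]],
                      width = 7, height = 5)
    }
    return(invisible(plots))
  }
  plots
}
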