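#' Run a grouped nanoclustering analysis end-to-end
#'
#' Ingests coordinate tables for one or more conditions, runs the
#' univariate (or bivariate) pipeline on every image, and writes per-image
#' curves, `Lmax`/LBI tables, oligomer distributions, group summaries
#' (mean +/- SEM), pairwise permutation tests, and a JSON manifest
#' capturing every parameter, seed and input file. Re-running from the
#' manifest reproduces all result tables byte-identically.
#'
#' @param config A named list, or a path to a YAML (or manifest JSON) file,
#'   with fields:
#' \describe{
#'   \item{analysis}{`"univariate"` (default) or `"bivariate"`.}
#'   \item{conditions}{Named list. Univariate: each entry a directory (or
#'     character vector of files) of coordinate CSVs, one per image.
#'     Bivariate: each entry a list with `big` and `small` directories
#'     whose sorted file lists are paired by position.}
#'   \item{region}{`c(width, height)` in nm; default `c(1000, 1000)`.}
#'   \item{pixel_size}{nm per pixel for the input tables; default 1.}
#'   \item{grid}{`c(from, to, by)` in nm; default `c(1, 240, 1)`.}
#'   \item{level}{Envelope level; default 0.99 univariate, 0.95 bivariate.}
#'   \item{n_sims}{Envelope simulations; default 1000.}
#'   \item{n_boot}{Permutations for the group tests; default 1000.}
#'   \item{oligomer_threshold}{nm; default 15 (univariate only).}
#'   \item{seed}{Integer seed.}
#'   \item{out_dir}{Output directory (created if missing).}
#' }
#' @return A `nanoclust_bundle` list with the result tibbles, the resolved
#'   config, and the output paths.
#' @export
run_group_analysis <- function(config) {
  cfg <- resolve_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  bundle <- if (cfg$analysis == "univariate") {
    run_univariate_analysis(cfg)
  } else {
    run_bivariate_analysis(cfg)
  }
  manifest_path <- file.path(cfg$out_dir, "manifest.json")
  jsonlite::write_json(cfg, manifest_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  bundle$manifest <- cfg
  bundle$paths <- c(bundle$paths, manifest = manifest_path)
  class(bundle) <- "nanoclust_bundle"
  bundle
}

resolve_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- if (grepl("\\.json$", config, ignore.case = TRUE)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
    # a manifest read back can carry its resolved file lists as data frames;
    # coerce to plain lists of character vectors
  }
  stopifnot(is.list(config))
  cfg <- config
  cfg$analysis <- match.arg(cfg$analysis %||% "univariate",
                            c("univariate", "bivariate"))
  cfg$region <- as.numeric(cfg$region %||% c(1000, 1000))
  cfg$pixel_size <- cfg$pixel_size %||% 1
  cfg$grid <- as.numeric(cfg$grid %||% c(1, 240, 1))
  cfg$level <- cfg$level %||% if (cfg$analysis == "univariate") 0.99 else 0.95
  cfg$n_sims <- cfg$n_sims %||% 1000
  cfg$n_boot <- cfg$n_boot %||% 1000
  cfg$oligomer_threshold <- cfg$oligomer_threshold %||% 15
  cfg$seed <- cfg$seed %||% 1
  if (is.null(cfg$out_dir)) {
    stop("run_group_analysis: config must name an out_dir", call. = FALSE)
  }
  if (is.null(cfg$conditions) || length(cfg$conditions) < 1 ||
      is.null(names(cfg$conditions))) {
    stop("run_group_analysis: config needs a named `conditions` list",
         call. = FALSE)
  }
  # resolve every directory to an explicit sorted file list up front so the
  # manifest is replayable and missing inputs fail before any output is made
  expand <- function(x) {
    x <- unlist(x, use.names = FALSE)
    files <- unlist(lapply(x, function(p) {
      if (dir.exists(p)) {
        list.files(p, pattern = "\\.(csv|tsv|txt)$", full.names = TRUE)
      } else {
        p
      }
    }), use.names = FALSE)
    files <- sort(files)
    if (length(files) == 0) {
      stop("run_group_analysis: no coordinate files found for a condition",
           call. = FALSE)
    }
    missing <- files[!file.exists(files)]
    if (length(missing) > 0) {
      stop(sprintf("run_group_analysis: missing input file(s): %s",
                   paste(utils::head(missing, 3), collapse = ", ")),
           call. = FALSE)
    }
    files
  }
  cfg$conditions <- lapply(cfg$conditions, function(cond) {
    if (cfg$analysis == "bivariate") {
      if (!all(c("big", "small") %in% names(cond))) {
        stop("run_group_analysis: bivariate conditions need `big` and `small` inputs",
             call. = FALSE)
      }
      big <- expand(cond$big)
      small <- expand(cond$small)
      if (length(big) != length(small)) {
        stop("run_group_analysis: big and small channels have unequal image counts",
             call. = FALSE)
      }
      list(big = big, small = small)
    } else {
      expand(cond)
    }
  })
  cfg$package_version <- as.character(utils::packageVersion("nanoclust"))
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

cfg_region <- function(cfg) study_region(0, 0, cfg$region[1], cfg$region[2])
cfg_grid <- function(cfg) {
  radius_grid(seq(cfg$grid[1], cfg$grid[2], by = cfg$grid[3]))
}

run_univariate_analysis <- function(cfg) {
  region <- cfg_region(cfg)
  grid <- cfg_grid(cfg)
  conds <- names(cfg$conditions)

  per_cond <- lapply(conds, function(nm) {
    files <- cfg$conditions[[nm]]
    patterns <- lapply(files, read_point_table, pixel_size = cfg$pixel_size,
                       region = region, channel = nm)
    lm_tbl <- group_lmax(patterns, grid, level = cfg$level,
                         n_sims = cfg$n_sims, seed = cfg$seed)
    lm_tbl$condition <- nm
    lm_tbl$file <- basename(files)
    curves <- purrr::map_dfr(seq_along(patterns), function(i) {
      cv <- k_function(patterns[[i]], grid)
      tibble::tibble(condition = nm, image = i, r = cv$r, k = cv$k,
                     l_minus_r = cv$l_minus_r)
    })
    olig <- purrr::map_dfr(seq_along(patterns), function(i) {
      od <- classify_oligomers(patterns[[i]],
                               threshold = cfg$oligomer_threshold)
      dplyr::mutate(tibble::as_tibble(od), condition = nm, image = i,
                    .before = 1)
    })
    list(lmax = lm_tbl, curves = curves, oligomers = olig)
  })
  lmax_tbl <- dplyr::bind_rows(lapply(per_cond, `[[`, "lmax"))
  curves <- dplyr::bind_rows(lapply(per_cond, `[[`, "curves"))
  oligomers <- dplyr::bind_rows(lapply(per_cond, `[[`, "oligomers"))

  summary_tbl <- lmax_tbl |>
    dplyr::group_by(.data$condition) |>
    dplyr::group_modify(~ summarize_group(.x)) |>
    dplyr::ungroup()

  tests <- pairwise_tests(split(lmax_tbl$l_max, lmax_tbl$condition),
                          cfg$n_boot, cfg$seed)

  paths <- c(
    curves = write_results_table(curves, file.path(cfg$out_dir, "curves.csv")),
    lmax = write_results_table(lmax_tbl, file.path(cfg$out_dir, "lmax.csv")),
    oligomers = write_results_table(oligomers,
                                    file.path(cfg$out_dir, "oligomers.csv")),
    summary = write_results_table(summary_tbl,
                                  file.path(cfg$out_dir, "group_summary.csv")))
  if (nrow(tests) > 0) {
    paths <- c(paths, tests = write_results_table(
      tests, file.path(cfg$out_dir, "pairwise_tests.csv")))
  }
  list(analysis = "univariate", lmax = lmax_tbl, curves = curves,
       oligomers = oligomers, summary = summary_tbl, tests = tests,
       paths = paths)
}

run_bivariate_analysis <- function(cfg) {
  region <- cfg_region(cfg)
  grid <- cfg_grid(cfg)
  conds <- names(cfg$conditions)

  res <- purrr::map_dfr(conds, function(nm) {
    files <- cfg$conditions[[nm]]
    purrr::map_dfr(seq_along(files$big), function(i) {
      pair <- bivariate_pattern(
        read_point_table(files$big[i], cfg$pixel_size, region, "big"),
        read_point_table(files$small[i], cfg$pixel_size, region, "small"))
      tst <- lbi_test(pair, grid, level = cfg$level, n_sims = cfg$n_sims,
                      seed = cfg$seed)
      dplyr::mutate(tst$lbi, condition = nm, image = i,
                    file_big = basename(files$big[i]),
                    file_small = basename(files$small[i]), .before = 1)
    })
  })

  summary_tbl <- res |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(n_images = dplyr::n(), mean_lbi = mean(.data$lbi),
                     sem_lbi = stats::sd(.data$lbi) / sqrt(dplyr::n()))

  tests <- pairwise_tests(split(res$lbi, res$condition), cfg$n_boot, cfg$seed)

  paths <- c(
    lbi = write_results_table(res, file.path(cfg$out_dir, "lbi.csv")),
    summary = write_results_table(summary_tbl,
                                  file.path(cfg$out_dir, "group_summary.csv")))
  if (nrow(tests) > 0) {
    paths <- c(paths, tests = write_results_table(
      tests, file.path(cfg$out_dir, "pairwise_tests.csv")))
  }
  list(analysis = "bivariate", lbi = res, summary = summary_tbl,
       tests = tests, paths = paths)
}

pairwise_tests <- function(groups, n_boot, seed) {
  nms <- names(groups)
  if (length(nms) < 2) {
    return(tibble::tibble(condition_a = character(0),
                          condition_b = character(0),
                          statistic = numeric(0), p_value = numeric(0)))
  }
  combs <- utils::combn(nms, 2, simplify = FALSE)
  purrr::map_dfr(combs, function(ab) {
    tst <- bootstrap_group_test(groups[[ab[1]]], groups[[ab[2]]],
                                n_boot = n_boot, seed = seed)
    tibble::tibble(condition_a = ab[1], condition_b = ab[2],
                   statistic = tst$statistic, p_value = tst$p_value)
  })
}

#' @export
print.nanoclust_bundle <- function(x, ...) {
  cat(sprintf("<nanoclust_bundle> %s analysis, %d condition(s), outputs in %s\n",
              x$analysis, length(x$manifest$conditions),
              x$manifest$out_dir))
  invisible(x)
}
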