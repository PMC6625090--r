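#' Two-group permutation (bootstrap) test on per-image Lmax
#'
#' Compares the nanoclustering of two replicate groups (one `Lmax` per
#' micrograph region). The observed statistic is
#' `T = |mean Lmax(A) - mean Lmax(B)|`; a null distribution is built by
#' randomly permuting the pattern-to-group assignment (group sizes fixed)
#' `n_boot` times, and `p = (1 + #{T* >= T}) / (1 + n_boot)`.
#'
#' With `statistic = "curve_ssd"` the inputs are lists of standardized
#' curves (one per image) and the statistic is the integrated squared
#' difference between the group mean curves over their common defined
#' radii -- a whole-curve alternative to the peak summary.
#'
#' @param group_a,group_b Numeric vectors of per-image `Lmax` (or the
#'   tibbles from [group_lmax()], whose `l_max` column is used); for
#'   `"curve_ssd"`, lists of `std_curve` objects. Each group needs `>= 2`
#'   images.
#' @param n_boot Number of permutations (`>= 100`; default 1000).
#' @param seed Integer seed.
#' @param statistic `"mean_lmax"` (default) or `"curve_ssd"`.
#' @return A `nanoclust_test` object; see [tidy()] / [glance()].
#' @export
bootstrap_group_test <- function(group_a, group_b, n_boot = 1000, seed = 1,
                                 statistic = c("mean_lmax", "curve_ssd")) {
  statistic <- match.arg(statistic)
  stopifnot(n_boot >= 100)
  if (statistic == "mean_lmax") {
    a <- extract_lmax(group_a)
    b <- extract_lmax(group_b)
    if (length(a) < 2 || length(b) < 2) {
      stop("bootstrap_group_test: each group needs at least 2 images",
           call. = FALSE)
    }
    pooled <- c(a, b)
    na <- length(a)
    stat_fun <- function(idx_a) {
      abs(mean(pooled[idx_a]) - mean(pooled[-idx_a]))
    }
  } else {
    mat_a <- curves_matrix(group_a)
    mat_b <- curves_matrix(group_b)
    if (ncol(mat_a) < 2 || ncol(mat_b) < 2) {
      stop("bootstrap_group_test: each group needs at least 2 images",
           call. = FALSE)
    }
    if (nrow(mat_a) != nrow(mat_b)) {
      stop("bootstrap_group_test: groups must share one radius grid",
           call. = FALSE)
    }
    pooled_mat <- cbind(mat_a, mat_b)
    na <- ncol(mat_a)
    pooled <- seq_len(ncol(pooled_mat))
    stat_fun <- function(idx_a) {
      d <- rowMeans(pooled_mat[, idx_a, drop = FALSE], na.rm = TRUE) -
        rowMeans(pooled_mat[, -idx_a, drop = FALSE], na.rm = TRUE)
      sum(d^2, na.rm = TRUE)
    }
  }
  n_tot <- length(pooled)
  observed <- stat_fun(seq_len(na))
  t_star <- withr::with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      stat_fun(sample.int(n_tot, na))
    }, numeric(1))
  })
  p <- (1 + sum(t_star >= observed)) / (1 + n_boot)
  structure(
    list(statistic = observed, p_value = p, n_boot = n_boot,
         n_a = na, n_b = n_tot - na, seed = seed, kind = statistic),
    class = "nanoclust_test"
  )
}

extract_lmax <- function(g) {
  if (is.data.frame(g)) {
    stopifnot("l_max" %in% names(g))
    return(g$l_max)
  }
  stopifnot(is.numeric(g))
  as.numeric(g)
}

curves_matrix <- function(curves) {
  stopifnot(is.list(curves))
  vapply(curves, function(s) {
    stopifnot(is.data.frame(s), all(c("std", "defined") %in% names(s)))
    ifelse(s$defined, s$std, NA_real_)
  }, numeric(nrow(curves[[1]])))
}

#' @export
print.nanoclust_test <- function(x, ...) {
  cat(sprintf("<nanoclust_test> %s permutation test: T = %.4g, p = %.4g (%d vs %d images, %d permutations)\n",
              x$kind, x$statistic, x$p_value, x$n_a, x$n_b, x$n_boot))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.nanoclust_test <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, p_value = x$p_value,
                 method = paste0("permutation_", x$kind))
}

#' @export
glance.nanoclust_test <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, p_value = x$p_value,
                 n_boot = x$n_boot, n_a = x$n_a, n_b = x$n_b)
}

#' Group summary of per-image Lmax values
#'
#' Mean and SEM of `Lmax` over the micrograph regions of one condition.
#' The unweighted mean across images is the default; `weights = "n"`
#' weights each image by its gold count.
#'
#' @param lmax_tbl Tibble from [group_lmax()].
#' @param weights `"equal"` (default) or `"n"`.
#' @return One-row tibble: `n_images`, `mean_lmax`, `sem_lmax`.
#' @export
summarize_group <- function(lmax_tbl, weights = c("equal", "n")) {
  weights <- match.arg(weights)
  stopifnot(is.data.frame(lmax_tbl), "l_max" %in% names(lmax_tbl))
  v <- lmax_tbl$l_max
  m <- if (weights == "n") {
    stats::weighted.mean(v, lmax_tbl$n)
  } else {
    mean(v)
  }
  tibble::tibble(n_images = length(v), mean_lmax = m,
                 sem_lmax = stats::sd(v) / sqrt(length(v)))
}
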