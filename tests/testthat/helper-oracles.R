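# Independent brute-force oracles used to validate the vectorized
# estimators. Deliberately naive: explicit loops over point pairs, scalar
# edge weights, hand-rolled union-find.

oracle_k_curve <- function(pattern, radii) {
  x <- pattern$points$x
  y <- pattern$points$y
  n <- length(x)
  region <- pattern$region
  acc <- numeric(length(radii))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      d <- sqrt((x[i] - x[j])^2 + (y[i] - y[j])^2)
      if (d > max(radii)) next
      w <- edge_correction_weight(c(x[i], y[i]), d, region)
      acc <- acc + w * (d <= radii)
    }
  }
  region$area / n^2 * acc
}

oracle_biv_k <- function(pair, radii) {
  bx <- pair$big$points$x;   by <- pair$big$points$y
  sx <- pair$small$points$x; sy <- pair$small$points$y
  region <- pair$big$region
  kbs <- numeric(length(radii))
  ksb <- numeric(length(radii))
  for (i in seq_along(bx)) {
    for (j in seq_along(sx)) {
      d <- sqrt((bx[i] - sx[j])^2 + (by[i] - sy[j])^2)
      if (d > max(radii)) next
      hit <- d <= radii
      kbs <- kbs + edge_correction_weight(c(bx[i], by[i]), d, region) * hit
      ksb <- ksb + edge_correction_weight(c(sx[j], sy[j]), d, region) * hit
    }
  }
  scale <- region$area / (length(bx) * length(sx))
  kbs <- scale * kbs
  ksb <- scale * ksb
  (length(bx) * ksb + length(sx) * kbs) / (length(bx) + length(sx))
}

# union-find single-linkage components at a distance threshold
oracle_cluster_sizes <- function(x, y, threshold) {
  n <- length(x)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      if (sqrt((x[i] - x[j])^2 + (y[i] - y[j])^2) <= threshold) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  sort(as.integer(table(roots)))
}

# numerical circumference-sampling oracle for the edge weight
oracle_arc_weight <- function(center, r, region, n_samples = 1e5) {
  theta <- seq(0, 2 * pi, length.out = n_samples + 1)[-1]
  px <- center[1] + r * cos(theta)
  py <- center[2] + r * sin(theta)
  inside <- px >= region$x_min & px <= region$x_max &
    py >= region$y_min & py <= region$y_max
  1 / mean(inside)
}

random_pattern <- function(n, region = study_region(), seed = 1) {
  withr::with_seed(seed, {
    point_pattern(
      data.frame(x = stats::runif(n, region$x_min, region$x_max),
                 y = stats::runif(n, region$y_min, region$y_max)),
      region = region)
  })
}
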