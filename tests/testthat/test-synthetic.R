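test_that("all generators are bit-reproducible under a fixed seed", {
  expect_identical(simulate_csr(50, seed = 3)$points,
                   simulate_csr(50, seed = 3)$points)
  expect_identical(simulate_thomas(seed = 3)$points,
                   simulate_thomas(seed = 3)$points)
  cp <- curvature_params(0.5)
  expect_identical(simulate_curvature_response(cp, seed = 3)$points,
                   simulate_curvature_response(cp, seed = 3)$points)
  b1 <- simulate_bivariate("colocalized", seed = 3)
  b2 <- simulate_bivariate("colocalized", seed = 3)
  expect_identical(b1$big$points, b2$big$points)
  expect_identical(b1$small$points, b2$small$points)
  pp <- simulate_csr(100, seed = 4)
  expect_identical(thin_by_labeling(pp, 0.4, seed = 5)$points,
                   thin_by_labeling(pp, 0.4, seed = 5)$points)
})

test_that("CSR places exactly n uniform points", {
  expect_equal(simulate_csr(0, seed = 1)$n, 0)
  pp <- simulate_csr(250, seed = 2)
  expect_equal(pp$n, 250)
  expect_true(all(pp$points$x >= 0 & pp$points$x <= 1000))
})

test_that("the Thomas closed form hits its hand value and limits", {
  tp <- thomas_params()   # kappa 5e-5, sigma 10
  expect_equal(thomas_k_closed_form(tp, 20),
               pi * 400 + (1 - exp(-1)) * 20000, tolerance = 1e-12)
  expect_lt(thomas_k_closed_form(tp, 1e-4), 1e-3)       # K -> 0 as r -> 0
  dense <- thomas_params(kappa = 1e6)
  expect_equal(thomas_k_closed_form(dense, 50), pi * 2500,
               tolerance = 1e-3)                         # CSR limit
  expect_error(thomas_params(sigma = -1))
})

test_that("Thomas retained counts match the process expectation", {
  # kappa 5e-6 * 1e6 nm^2 * mu 5 = 25 expected points per image
  tp <- thomas_params(kappa = 5e-6)
  ns <- vapply(1:200, function(i) simulate_thomas(tp, seed = i)$n, numeric(1))
  expect_equal(mean(ns), 25, tolerance = 0.1)
  # default parameters give ~250 per 1 um^2
  nd <- vapply(1:50, function(i) simulate_thomas(seed = 1000 + i)$n,
               numeric(1))
  expect_equal(mean(nd), 250, tolerance = 0.1)
})

test_that("thinning behaves binomially and keeps everything at efficiency 1", {
  pp <- simulate_csr(200, seed = 6)
  expect_identical(thin_by_labeling(pp, 1, seed = 1)$points, pp$points)
  kept <- vapply(1:500, function(i) thin_by_labeling(pp, 0.3, seed = i)$n,
                 numeric(1))
  # mean over 500 thinnings of Binomial(200, 0.3): SE of the mean ~ 0.29
  expect_equal(mean(kept), 60, tolerance = 0.025)
  expect_error(thin_by_labeling(pp, 0))
})

test_that("curvature mixture interpolates between CSR and pure clustering", {
  reg <- study_region()
  p0 <- simulate_curvature_response(curvature_params(0, n_total = 150),
                                    reg, seed = 11)
  p1 <- simulate_curvature_response(curvature_params(1, n_total = 150),
                                    reg, seed = 11)
  expect_equal(p0$n, 150)
  expect_equal(p1$n, 150)
  # clustered patterns pack far more close pairs than CSR ones
  n_close <- function(p) sum(stats::dist(cbind(p$points$x, p$points$y)) < 20)
  expect_gt(n_close(p1), 5 * n_close(p0))
})

test_that("bivariate modes produce the intended cross-channel structure", {
  co <- simulate_bivariate("colocalized", n_b = 80, n_s = 80, seed = 13)
  seg <- simulate_bivariate("segregated", n_b = 80, n_s = 80, seed = 13)
  expect_equal(co$n_b, 80)
  expect_equal(co$n_s, 80)
  cross_close <- function(pr, r) {
    d <- sqrt(outer(pr$big$points$x, pr$small$points$x, "-")^2 +
                outer(pr$big$points$y, pr$small$points$y, "-")^2)
    sum(d <= r)
  }
  expect_gt(cross_close(co, 30), cross_close(seg, 30))
  expect_error(simulate_bivariate("nonsense"))
})

test_that("cluster-parameter fitting recovers sigma from pooled K curves", {
  tp <- thomas_params()
  pats <- lapply(1:10, function(i) simulate_thomas(tp, seed = 800 + i))
  fit <- fit_thomas(pats, grid = radius_grid(1:110))
  expect_equal(fit$sigma, 10, tolerance = 0.25)
  expect_s3_class(tidy(fit), "tbl_df")
  expect_equal(tidy(fit)$term, c("kappa", "sigma"))
})
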