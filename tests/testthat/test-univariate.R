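test_that("K estimator reproduces hand-computed pair sums", {
  pp <- point_pattern(data.frame(x = c(500, 500), y = c(490, 510)))
  kc <- k_function(pp, radius_grid(c(10, 25)))
  # both ordered pairs at distance 20, interior so w = 1:
  # K(25) = 1e6 * (1/4) * 2 = 5e5; no pair within 10 nm
  expect_equal(kc$k, c(0, 5e5))
  expect_equal(kc$l_minus_r, c(-10, sqrt(5e5 / pi) - 25))
  expect_error(k_function(point_pattern(data.frame(x = 1, y = 1))),
               "at least 2")
})

test_that("K is nondecreasing in r and matches the brute-force oracle", {
  radii <- radius_grid(seq(10, 240, by = 23))
  for (s in 1:10) {
    pp <- random_pattern(sample(5:30, 1), seed = s)
    kc <- k_function(pp, radius_grid())
    expect_true(all(diff(kc$k) >= 0))
    got <- k_function(pp, radii)$k
    want <- oracle_k_curve(pp, as.numeric(radii))
    expect_lt(max(abs(got - want) / pmax(want, 1e-12)), 1e-9)
  }
})

test_that("the L-transform maps K through sqrt(K/pi) - r", {
  tbl <- tibble::tibble(r = c(10, 50), k = c(0, pi * 50^2))
  out <- l_curve(tbl)
  expect_equal(out$l_minus_r, c(-10, 0))
  expect_error(l_curve(tibble::tibble(r = 1, k = -1)), "negative")
})

test_that("CSR envelopes are seeded, level-monotone and positive at moderate r", {
  reg <- study_region()
  grid <- radius_grid(c(25, 50, 100))
  e1 <- csr_envelope(50, reg, grid, 0.99, n_sims = 150, seed = 3)
  e2 <- csr_envelope(50, reg, grid, 0.99, n_sims = 150, seed = 3)
  expect_identical(e1$env, e2$env)
  e95 <- csr_envelope(50, reg, grid, 0.95, n_sims = 150, seed = 3)
  expect_true(all(e1$env >= e95$env))
  expect_gt(e1$env[grid == 50], 0)
  expect_error(csr_envelope(50, reg, grid, level = 1.2), "level")
})

test_that("standardization divides by the envelope and flags undefined radii", {
  grid <- radius_grid(c(10, 20, 30, 40))
  env <- structure(tibble::tibble(r = as.numeric(grid),
                                  env = c(0, 4, 2, 8)),
                   class = c("mc_envelope", "tbl_df", "tbl", "data.frame"),
                   level = 0.99)
  curve <- tibble::tibble(r = as.numeric(grid),
                          l_minus_r = c(5, 4, 4, 1.6))
  std <- standardize_curve(curve, env)
  expect_equal(std$defined, c(FALSE, TRUE, TRUE, TRUE))
  expect_equal(std$std[-1], c(1, 2, 0.2))
  expect_equal(attr(std, "l_max"), 2)
  expect_equal(attr(std, "r_at_max"), 30)

  # curve equal to the envelope standardizes to exactly 1 everywhere
  self <- standardize_curve(
    tibble::tibble(r = env$r, l_minus_r = env$env), env)
  expect_equal(self$std[self$defined], rep(1, 3))
  zero <- standardize_curve(
    tibble::tibble(r = env$r, l_minus_r = rep(0, 4)), env)
  expect_equal(lmax(zero)$l_max, 0)

  bad <- tibble::tibble(r = c(1, 2, 3, 5), l_minus_r = 0)
  expect_error(standardize_curve(bad, env), "grids differ")
})

test_that("Lmax takes the peak and breaks ties toward the smaller radius", {
  std <- tibble::tibble(r = c(10, 20, 30, 40),
                        std = c(0.5, 1.8, 1.8, 0.2),
                        defined = TRUE)
  pk <- lmax(std)
  expect_equal(pk$l_max, 1.8)
  expect_equal(pk$r_at_max, 20)
  none <- tibble::tibble(r = 1, std = NA_real_, defined = FALSE)
  expect_error(lmax(none), "no defined radii")
})

test_that("group_lmax shares envelopes across equal counts and is reproducible", {
  reg <- study_region()
  grid <- radius_grid(seq(10, 120, by = 10))
  pats <- lapply(1:3, function(i) simulate_csr(40, reg, seed = 100 + i))
  a <- group_lmax(pats, grid, n_sims = 120, seed = 9)
  b <- group_lmax(pats, grid, n_sims = 120, seed = 9)
  expect_identical(a, b)
  expect_equal(nrow(a), 3)
  expect_true(all(c("l_max", "l_max_raw", "r_at_max") %in% names(a)))
  # mixed regions refuse to pool
  other <- simulate_csr(40, study_region(0, 0, 500, 500), seed = 1)
  expect_error(group_lmax(c(pats, list(other)), grid), "region dimensions")
})
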