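test_that("study regions enforce their geometry and report area", {
  reg <- study_region()
  expect_equal(reg$area, 1e6)
  expect_equal(study_region(0, 0, 500, 2000)$area, 1e6)
  expect_error(study_region(0, 0, 0, 100), "exceed")
  expect_error(study_region(10, 0, 5, 100), "exceed")
})

test_that("point patterns validate coordinates against a closed region", {
  reg <- study_region()
  pp <- point_pattern(data.frame(x = c(0, 1000), y = c(0, 1000)), reg)
  expect_equal(pp$n, 2)  # boundary points are inside
  expect_error(point_pattern(data.frame(x = 1001, y = 5), reg),
               "outside the study region")
  expect_error(point_pattern(data.frame(x = 1, y = NA), reg), "missing")
  empty <- point_pattern(data.frame(x = numeric(0), y = numeric(0)), reg)
  expect_equal(empty$n, 0)
})

test_that("bivariate patterns require a shared region", {
  a <- point_pattern(data.frame(x = 1, y = 1), study_region())
  b <- point_pattern(data.frame(x = 1, y = 1), study_region(0, 0, 500, 500))
  expect_error(bivariate_pattern(a, b), "share")
  pair <- bivariate_pattern(a, point_pattern(data.frame(x = 2, y = 2)))
  expect_equal(pair$n_b, 1)
  expect_equal(pair$n_s, 1)
})

test_that("coordinate tables read with pixel conversion and validation", {
  reg <- study_region()
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("x,y", "100,200", "300,400"), f)
  pp <- read_point_table(f, pixel_size = 1, region = reg)
  expect_equal(pp$n, 2)
  expect_equal(pp$points$x, c(100, 300))

  # ImageJ-style pixel columns with conversion
  writeLines(c("X,Y", "50,50"), f)
  pp2 <- read_point_table(f, pixel_size = 2.2, region = reg)
  expect_equal(pp2$points$x, 110)
  expect_equal(pp2$points$y, 110)

  writeLines("x,y", f)
  expect_equal(read_point_table(f, region = reg)$n, 0)

  writeLines(c("a,b", "1,2"), f)
  expect_error(read_point_table(f, region = reg), "coordinate columns")

  writeLines(c("x,y", "50,50"), f)
  expect_error(read_point_table(f, pixel_size = 25, region = reg),
               "outside the study region")
})

test_that("results tables round-trip at full precision", {
  f <- withr::local_tempfile(fileext = ".csv")
  tbl <- tibble::tibble(r = seq_len(240),
                        l_minus_r = sin(seq_len(240)) * exp(1))
  write_results_table(tbl, f)
  back <- readr::read_csv(f, show_col_types = FALSE)
  expect_equal(back$l_minus_r, tbl$l_minus_r)
  expect_error(write_results_table(tbl[0, ], f), "at least one row")
})

test_that("edge weights hit the exact symmetric cases", {
  reg <- study_region()
  expect_equal(edge_correction_weight(c(500, 500), 100, reg), 1)
  expect_equal(edge_correction_weight(c(0, 500), 5, reg), 2)
  expect_equal(edge_correction_weight(c(1000, 500), 5, reg), 2)
  expect_equal(edge_correction_weight(c(0, 0), 5, reg), 4)
  expect_equal(edge_correction_weight(c(1000, 1000), 5, reg), 4)
  expect_error(edge_correction_weight(c(-1, 500), 5, reg), "outside")
})

test_that("edge weights are >= 1, exactly 1 for interior circles, and match arc sampling", {
  reg <- study_region()
  withr::with_seed(99, {
    for (k in 1:100) {
      cx <- runif(1, 0, 1000)
      cy <- runif(1, 0, 1000)
      r <- runif(1, 1, 240)
      w <- edge_correction_weight(c(cx, cy), r, reg)
      expect_gte(w, 1)
      if (min(cx, 1000 - cx, cy, 1000 - cy) > r) expect_equal(w, 1)
    }
  })
  # closed form vs circumference sampling on random boundary-crossing draws
  withr::with_seed(7, {
    for (k in 1:20) {
      cx <- runif(1, 0, 100)  # near the left edge so circles cross it
      cy <- runif(1, 0, 1000)
      r <- runif(1, 50, 240)
      w <- edge_correction_weight(c(cx, cy), r, reg)
      w_mc <- oracle_arc_weight(c(cx, cy), r, reg)
      expect_lt(abs(w - w_mc) / w_mc, 1e-3)
    }
  })
})
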