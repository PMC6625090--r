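test_that("Rq roughness matches hand values and is offset/ramp invariant", {
  expect_equal(rq_roughness(matrix(c(1, -1, 1, -1), 2)), 1)
  expect_equal(rq_roughness(matrix(c(0, 0, 3, 3), 2)), 1.5)
  m <- matrix(rnorm(64), 8)
  expect_equal(rq_roughness(m + 42), rq_roughness(m))
  expect_equal(rq_roughness(matrix(5, 4, 4)), 0)  # flat map
  # a pure linear ramp levels to ~0 under plane fitting but not mean
  ramp <- outer(1:10, 1:10, function(i, j) 3 * i + 2 * j)
  expect_lt(rq_roughness(ramp, leveling = "plane"), 1e-8)
  expect_gt(rq_roughness(ramp, leveling = "mean"), 1)
})

test_that("FRET efficiency is the fractional donor-lifetime shortening", {
  d <- data.frame(tau_donor_only = c(2.5, 2.0, 2.5),
                  tau_donor_acceptor = c(2.5, 2.0, 1.5))
  out <- fret_efficiency(d)
  expect_equal(out$efficiency, c(0, 0, 0.4))
  # strictly decreasing in tau_DA at fixed tau_D
  seqd <- data.frame(tau_donor_only = 2.5,
                     tau_donor_acceptor = seq(2.4, 0.1, by = -0.1))
  expect_true(all(diff(fret_efficiency(seqd)$efficiency) > 0))
  expect_warning(
    fret_efficiency(data.frame(tau_donor_only = 2,
                               tau_donor_acceptor = 2.2)), "tau_DA")
  expect_error(
    fret_efficiency(data.frame(tau_donor_only = 0,
                               tau_donor_acceptor = 1)), "positive")
})

make_bar_image <- function(geometry, nr, nc, cap = 200, center = 100,
                           bg = 50) {
  img <- matrix(bg, nr, nc)
  masks <- nanoclust:::nanobar_masks(img, geometry)
  img[masks$center] <- center
  img[masks$ends] <- cap
  img
}

test_that("nanobar end/center ratio reads constructed cap enhancement", {
  geo <- nanobar_geometry(center = c(120, 40), angle = 0, pixel_size = 10)
  img <- make_bar_image(geo, 80, 240)
  out <- nanobar_end_center_ratio(img, geo)
  expect_equal(out$ratio, 2)
  # end and center regions are designed with equal areas (within
  # pixelation of the pi R^2 cap area)
  expect_equal(out$end_px, out$center_px, tolerance = 0.05)
  # uniform image gives exactly 1 wherever the bar sits
  expect_equal(nanobar_end_center_ratio(matrix(7, 80, 240), geo)$ratio, 1)
  # rotating the geometry with the image leaves the ratio unchanged
  geo90 <- nanobar_geometry(center = c(40, 120), angle = 90, pixel_size = 10)
  img90 <- make_bar_image(geo90, 240, 80)
  expect_equal(nanobar_end_center_ratio(img90, geo90)$ratio, 2)
  expect_error(
    nanobar_end_center_ratio(matrix(0, 80, 240), geo), "non-positive")
})

test_that("nanobar heat maps average pixelwise and suppress noise", {
  a <- matrix(1:6, 2)
  expect_equal(nanobar_heatmap(list(a, a)), a)
  expect_equal(nanobar_heatmap(list(a, 3 * a)), 2 * a)
  expect_error(nanobar_heatmap(list(a, matrix(0, 3, 2))), "dimensions")

  geo <- nanobar_geometry(center = c(60, 25), angle = 0, pixel_size = 20)
  clean <- make_bar_image(geo, 50, 120, cap = 150, center = 100, bg = 0)
  imgs <- withr::with_seed(31, {
    lapply(1:300, function(i) clean + matrix(rnorm(50 * 120, 0, 30), 50))
  })
  # heat-map averaging recovers the clean cap enhancement from heavy noise
  hm <- nanobar_heatmap(imgs)
  out <- nanobar_end_center_ratio(hm, geo)
  expect_equal(out$ratio, 1.5, tolerance = 0.05)
})

test_that("rolling-ball style background subtraction removes flat background", {
  flat <- matrix(13, 20, 20)
  expect_equal(subtract_background(flat), matrix(0, 20, 20))
  # a single-pixel spot on constant background survives; background -> 0
  img <- matrix(10, 20, 20)
  img[10, 10] <- 100
  out <- subtract_background(img, radius = 3)
  expect_gte(out[10, 10], 90)
  expect_equal(out[1, 1], 0)
  # idempotent on the flat-background case
  expect_equal(subtract_background(out, radius = 3), out)
})

test_that("SPR tables normalize by lipid response and sort isotherms", {
  rec <- data.frame(ru_solute = c(50, 30, 40), ru_lipid = c(1000, 1000, 800),
                    concentration = c(10, 1, 5), vesicle_diameter = 100)
  out <- spr_binding_table(rec)
  expect_equal(out$concentration, c(1, 5, 10))
  expect_equal(out$ratio[out$concentration == 10], 0.05)
  # scale invariance of the ratio
  rec2 <- rec
  rec2$ru_solute <- rec2$ru_solute * 2
  rec2$ru_lipid <- rec2$ru_lipid * 2
  expect_equal(spr_binding_table(rec2)$ratio, out$ratio)
  rec$ru_lipid[1] <- 0
  expect_error(spr_binding_table(rec), "positive")
})
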