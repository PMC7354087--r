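test_that("HU calibration anchors water at 0, air at -1000, midpoint at -500", {
  raw <- array(c(120, 20, 70, 500, -400), dim = c(5, 1, 1))
  cal <- calibrate_hu(raw, water_raw_mean = 120, air_raw_mean = 20)
  expect_equal(as.numeric(cal$voxels[1:3]), c(0, -1000, -500))
  expect_equal(as.numeric(cal$voxels[4]), 1000)   # clamp above
  expect_equal(as.numeric(cal$voxels[5]), -1000)  # clamp below
  expect_error(calibrate_hu(raw, 5, 5), "degenerate calibration")
})

test_that("calibration is invariant to affine distortion of the raw scale", {
  set.seed(12)
  raw <- array(rnorm(4^3, 50, 30), dim = c(4, 4, 4))
  cal0 <- calibrate_hu(raw, 80, 10)
  for (gain in c(0.5, 2, -1.3)) {
    dist <- gain * raw + 17
    cal1 <- calibrate_hu(dist, gain * 80 + 17, gain * 10 + 17)
    expect_equal(cal1$voxels, cal0$voxels)
  }
})

test_that("lung windowing keeps exactly the in-window voxels", {
  hu <- array(-400, dim = c(10, 10, 1))
  hu[1:1, , 1] <- 300                       # bone-like slab
  mask <- segment_lung(hu, c(-900, -100))
  expect_equal(sum(mask), 90)
  expect_true(all(hu[mask] == -400))
  expect_equal(mean_hu(hu, array(TRUE, dim(hu)), mask)$mean_hu, -400)
  expect_warning(segment_lung(array(500, c(2, 2, 2))), "empty lung")
  expect_equal(sum(segment_lung(array(-400, c(3, 3, 3)))), 27)
})

test_that("mean HU is invariant to VOI padding with out-of-window voxels", {
  hu <- array(-300, dim = c(6, 6, 6))
  hu[, , 6] <- 200
  voi_small <- array(FALSE, dim(hu)); voi_small[, , 1:5] <- TRUE
  voi_big <- array(TRUE, dim(hu))
  lung <- segment_lung(hu)
  expect_equal(mean_hu(hu, voi_small, lung)$mean_hu,
               mean_hu(hu, voi_big, lung)$mean_hu)
  expect_error(mean_hu(hu, array(FALSE, dim(hu))), "no lung in VOI")
})

test_that("T2 ratios divide region means and are gain invariant", {
  mr <- generate_mr_slice(lung_level = 300, muscle_level = 250,
                          kidney_level = 280, noise_sd = 0, seed = 1)
  res <- t2_ratio(mr)
  expect_equal(res$ratio_lung, 1.2)
  expect_equal(res$ratio_kidney, 1.12)
  scaled <- mr; scaled$image <- mr$image * 7.7
  expect_equal(t2_ratio(scaled)$ratio_lung, res$ratio_lung)
  nok <- mr; nok$labels[nok$labels == 2L] <- 0L
  expect_error(t2_ratio(nok), "muscle ROI")
  nokid <- mr; nokid$labels[nokid$labels == 3L] <- 0L
  expect_true(is.na(t2_ratio(nokid)$ratio_kidney))
})

test_that("percent change handles identity, decline and signed series", {
  expect_equal(percent_change(c(20, 19), c(0, 6))[["6"]], -5)
  expect_equal(percent_change(c(20, 20), c(0, 6))[["6"]], 0)
  # lung HU series: both values negative, magnitude grows by 11.79%
  expect_equal(percent_change(c(-357, -399.1), c(0, 12))[["12"]],
               100 * (-399.1 + 357) / (-357))
  expect_gt(percent_change(c(-357, -399.1), c(0, 12))[["12"]], 0)
  expect_warning(res <- percent_change(c(5, 6), c(6, 12)), "baseline")
  expect_null(res)
  expect_error(percent_change(c(0, 5), c(0, 6)), "zero baseline")
})
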