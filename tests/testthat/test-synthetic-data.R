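test_that("generators are deterministic under a fixed seed", {
  a <- generate_alveolar_section("voronoi_foam", size_px = 300,
                                 pixel_size_um = 2, seed = 9)
  b <- generate_alveolar_section("voronoi_foam", size_px = 300,
                                 pixel_size_um = 2, seed = 9)
  expect_identical(a$section$tissue_mask, b$section$tissue_mask)
  expect_identical(a$truth, b$truth)
  c1 <- inject_leukocyte_foci(list(width_um = 3000, height_um = 3000),
                              n_foci = 2, seed = 5)
  c2 <- inject_leukocyte_foci(list(width_um = 3000, height_um = 3000),
                              n_foci = 2, seed = 5)
  expect_identical(c1$points$x_um, c2$points$x_um)
  v1 <- generate_ct_volume(seed = 3, noise_sd_hu = 10)
  v2 <- generate_ct_volume(seed = 3, noise_sd_hu = 10)
  expect_identical(v1$raw, v2$raw)
  m1 <- generate_mr_slice(seed = 4, noise_sd = 2)
  m2 <- generate_mr_slice(seed = 4, noise_sd = 2)
  expect_identical(m1$image, m2$image)
})

test_that("generator argument validation catches degenerate geometry", {
  expect_error(generate_alveolar_section(period_um = 3, septum_um = 1,
                                         pixel_size_um = 2, size_px = 50),
               "degenerate geometry")
  expect_error(generate_alveolar_section(period_um = 10, septum_um = 20,
                                         size_px = 50),
               "period_um > septum_um")
  expect_error(generate_mr_slice(muscle_level = 0), "muscle_level")
  expect_error(generate_ct_volume(shape = c(8, 8, 8)), "at least 16")
  expect_error(inject_leukocyte_foci(list(width_um = 300, height_um = 300),
                                     n_foci = 50, seed = 1),
               "placement failure")
})

test_that("foam mean chord length strictly increases with emphysema fraction", {
  for (seed in 1:3) {
    lms <- sapply(c(0, 0.25, 0.5), function(f)
      generate_alveolar_section("voronoi_foam", emphysema_fraction = f,
                                size_px = 500, pixel_size_um = 2,
                                seed = seed)$truth$true_mean_chord_um)
    expect_true(all(diff(lms) > 0))
  }
})

test_that("matched-seed foam masks are nested: walls only disappear with severity", {
  a <- generate_alveolar_section("voronoi_foam", emphysema_fraction = 0,
                                 size_px = 300, pixel_size_um = 2, seed = 2)
  b <- generate_alveolar_section("voronoi_foam", emphysema_fraction = 0.4,
                                 size_px = 300, pixel_size_um = 2, seed = 2)
  expect_true(all(b$section$tissue_mask <= a$section$tissue_mask))
})

test_that("injected point sets have the promised structure", {
  empty <- inject_leukocyte_foci(list(width_um = 2000, height_um = 2000),
                                 n_foci = 0, background_density_per_mm2 = 0,
                                 seed = 1)
  expect_length(empty$points$x_um, 0)
  expect_equal(detect_foci(empty$points)$n_foci, 0)
  inj <- inject_leukocyte_foci(list(width_um = 5000, height_um = 5000),
                               n_foci = 3, cells_per_focus = 25, seed = 8)
  expect_equal(detect_foci(inj$points)$n_foci, 3)
  expect_equal(inj$points$section_area_mm2, 25)
})

test_that("noiseless CT round trip recovers the lung HU and anchors exactly", {
  ct <- generate_ct_volume(lung_mean_hu = -400, noise_sd_hu = 0, seed = 6)
  cal <- calibrate_hu(ct$raw, mean(ct$raw[ct$labels == 4L]),
                      mean(ct$raw[ct$labels == 5L]))
  expect_equal(mean(cal$voxels[ct$labels == 4L]), 0)
  expect_equal(mean(cal$voxels[ct$labels == 5L]), -1000)
  expect_equal(mean_hu(cal, ct$voi)$mean_hu, -400)
  expect_false(ct$truth$gain == 1 && ct$truth$offset == 0)
})

test_that("noisy CT mean HU stays within the standard-error bound", {
  # mean over an n-voxel VOI of HU noise sd 20 has SE 20/sqrt(n)
  fails <- 0L
  for (seed in 1:40) {
    ct <- generate_ct_volume(lung_mean_hu = -400, noise_sd_hu = 20,
                             seed = seed)
    cal <- calibrate_hu(ct$raw, mean(ct$raw[ct$labels == 4L]),
                        mean(ct$raw[ct$labels == 5L]))
    res <- mean_hu(cal, ct$voi)
    bound <- 3 * 20 / sqrt(res$n_voxels_used) + 3 * 20 / sqrt(sum(ct$labels == 4L))
    if (abs(res$mean_hu + 400) > bound) fails <- fails + 1L
  }
  expect_lte(fails, 1L)
})

test_that("noiseless MR round trip returns the constructed ratios", {
  mr <- generate_mr_slice(lung_level = 300, muscle_level = 250,
                          noise_sd = 0, seed = 2)
  expect_equal(t2_ratio(mr)$ratio_lung, 1.2)
  same <- generate_mr_slice(lung_level = 250, muscle_level = 250,
                            noise_sd = 0, seed = 2)
  expect_equal(t2_ratio(same)$ratio_lung, 1)
  up <- generate_mr_slice(lung_level = 318, muscle_level = 250,
                          noise_sd = 0, seed = 2)
  expect_equal(t2_ratio(up)$ratio_lung, 1.272)
  # 27.2% above a lung = muscle reference slice
  expect_equal(100 * (t2_ratio(up)$ratio_lung / t2_ratio(same)$ratio_lung - 1),
               27.2, tolerance = 1e-9)
  expect_equal(up$truth$true_t2_ratio, 1.272)
})
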