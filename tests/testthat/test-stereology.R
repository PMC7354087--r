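test_that("chord multiset at 1 px spacing equals the run-length oracle exactly", {
  for (seed in 1:5) {
    mask <- random_mask(40, 55, p_tissue = 0.5, seed = seed)
    sec <- make_section(mask, pixel_size_um = 2)
    got <- c(measure_chords(sec, NULL, "horizontal", line_spacing_um = 2,
                            min_chord_um = 4)$lengths_um,
             measure_chords(sec, NULL, "vertical", line_spacing_um = 2,
                            min_chord_um = 4)$lengths_um)
    expect_equal(sort(got), sort(oracle_all_chords(mask, 2, 4)))
  }
})

test_that("parallel-septa phantom yields only period-minus-septum chords", {
  ph <- generate_alveolar_section("parallel_septa", period_um = 50,
                                  septum_um = 10, size_px = 260,
                                  pixel_size_um = 1, seed = 1)
  cs <- measure_chords(ph$section, NULL, "horizontal", line_spacing_um = 25)
  expect_gt(length(cs$lengths_um), 0)
  expect_true(all(cs$lengths_um == 40))
  expect_equal(ph$truth$true_mean_chord_um, 40)
})

test_that("fully-tissue fields yield an empty chord set and an undefined Lm", {
  sec <- make_section(matrix(TRUE, 60, 60))
  cs <- measure_chords(sec, NULL, "horizontal", line_spacing_um = 10)
  expect_length(cs$lengths_um, 0)
  res <- compute_lm(sec, n_fields = 2, field_size_um = 20,
                    line_spacing_um = 5)
  expect_true(res$undefined)
  expect_true(is.na(res$lm_um))
})

test_that("field selection respects the exclusion mask and non-overlap", {
  mask <- matrix(FALSE, 120, 240)
  excl <- matrix(FALSE, 120, 240)
  excl[, 1:120] <- TRUE                       # left half excluded
  sec <- histology_section(mask, 1, exclusion_mask = excl)
  flds <- select_fields(sec, n_fields = 4, field_size_px = 30, seed = 2)
  expect_equal(nrow(flds), 4)
  for (i in seq_len(nrow(flds))) {
    r <- flds$row0[i]; c <- flds$col0[i]
    expect_false(any(excl[r:(r + 29), c:(c + 29)]))
  }
  # brute-force overlap check
  for (i in seq_len(nrow(flds) - 1)) for (j in (i + 1):nrow(flds)) {
    sep_r <- abs(flds$row0[i] - flds$row0[j]) >= 30
    sep_c <- abs(flds$col0[i] - flds$col0[j]) >= 30
    expect_true(sep_r || sep_c)
  }
  excl_all <- histology_section(mask, 1,
                                exclusion_mask = matrix(TRUE, 120, 240))
  expect_error(select_fields(excl_all, 2, 30, seed = 1), "no usable field")
})

test_that("Lm averages hierarchically without weighting", {
  # two fields with means 30 and 50 and unequal chord counts: section mean 40
  mask <- matrix(TRUE, 60, 120)
  mask[6, 2:31] <- FALSE                        # one 30 px chord, field 1
  mask[6, 62:81] <- FALSE                       # 20 px and 40 px... build 50 mean
  mask[14, 62:111] <- FALSE                     # 50 px chord, field 2
  sec <- histology_section(mask, 1)
  f1 <- list(row0 = 1L, col0 = 1L, size_px = 60L)
  f2 <- list(row0 = 1L, col0 = 61L, size_px = 60L)
  m1 <- measure_chords(sec, f1, "horizontal", line_spacing_um = 1)$lengths_um
  m2 <- measure_chords(sec, f2, "horizontal", line_spacing_um = 1)$lengths_um
  expect_equal(mean(m1), 30)
  expect_equal(mean(m2), 35)                    # (20 + 50) / 2
  # hierarchical rule at section level: unweighted mean of field means
  expect_equal(mean(c(mean(m1), mean(m2))), 32.5)
})

test_that("Lm scales exactly with pixel size when lengths scale together", {
  mask <- random_mask(80, 80, p_tissue = 0.45, seed = 4)
  s1 <- make_section(mask, pixel_size_um = 1)
  s2 <- make_section(mask, pixel_size_um = 2)
  c1 <- measure_chords(s1, NULL, "horizontal", line_spacing_um = 5,
                       min_chord_um = 6)$lengths_um
  c2 <- measure_chords(s2, NULL, "horizontal", line_spacing_um = 10,
                       min_chord_um = 12)$lengths_um
  expect_equal(sort(c2), sort(2 * c1))
})

test_that("raising the minimum chord length only removes chords and Lm is non-decreasing", {
  mask <- random_mask(100, 100, p_tissue = 0.35, seed = 6)
  sec <- make_section(mask, pixel_size_um = 2)
  prev <- NULL
  prev_mean <- -Inf
  for (mc in c(4, 10, 20, 30)) {
    ch <- measure_chords(sec, NULL, "horizontal", line_spacing_um = 6,
                         min_chord_um = mc)$lengths_um
    if (!is.null(prev)) expect_true(all(ch %in% prev))
    if (length(ch)) {
      expect_gte(mean(ch), prev_mean)
      prev_mean <- mean(ch)
    }
    prev <- ch
  }
})

test_that("horizontal and vertical Lm agree on isotropic foam", {
  diffs <- sapply(1:6, function(s) {
    fm <- generate_alveolar_section("voronoi_foam", size_px = 500,
                                    pixel_size_um = 2, seed = s)
    h <- measure_chords(fm$section, NULL, "horizontal", 50)$lengths_um
    v <- measure_chords(fm$section, NULL, "vertical", 50)$lengths_um
    (mean(h) - mean(v)) / mean(c(h, v))
  })
  expect_lt(abs(mean(diffs)), 0.02)
})
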