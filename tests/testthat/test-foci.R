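test_that("single-linkage components match the all-pairs union-find oracle", {
  set.seed(21)
  for (rep in 1:5) {
    n <- sample(50:150, 1)
    # mixture of clumps and scatter so components are nontrivial
    cx <- runif(4, 0, 2000); cy <- runif(4, 0, 2000)
    k <- sample.int(4, n, replace = TRUE)
    x <- cx[k] + rnorm(n, 0, 30); y <- cy[k] + rnorm(n, 0, 30)
    pts <- leukocyte_points(x, y, 4)
    det <- detect_foci(pts, linking_radius_um = 40, min_cells = 1)
    oracle <- oracle_components(x, y, 40)
    got <- integer(n)
    for (i in seq_along(det$foci_members)) got[det$foci_members[[i]]] <- i
    # same partition: equal label co-membership
    expect_equal(outer(got, got, "=="), outer(oracle, oracle, "=="))
  }
})

test_that("the focus rule is strictly more than 20 cells", {
  set.seed(2)
  x20 <- runif(20, 0, 10); y20 <- runif(20, 0, 10)
  expect_equal(detect_foci(leukocyte_points(x20, y20, 1))$n_foci, 0)
  x25 <- runif(25, 0, 18); y25 <- runif(25, 0, 18)
  expect_equal(detect_foci(leukocyte_points(x25, y25, 1))$n_foci, 1)
  x21 <- seq(0, 200, by = 10); y21 <- rep(0, 21)
  expect_equal(detect_foci(leukocyte_points(x21, y21, 1))$n_foci, 1)
})

test_that("focus counts are invariant to translation and rotation", {
  inj <- inject_leukocyte_foci(list(width_um = 5000, height_um = 5000),
                               n_foci = 4, seed = 13)
  x <- inj$points$x_um; y <- inj$points$y_um
  base <- detect_foci(inj$points)$n_foci
  shifted <- leukocyte_points(x + 1234.5, y - 321.7, 25)
  expect_equal(detect_foci(shifted)$n_foci, base)
  th <- 0.7
  rot <- leukocyte_points(x * cos(th) - y * sin(th),
                          x * sin(th) + y * cos(th), 25)
  expect_equal(detect_foci(rot)$n_foci, base)
})

test_that("growing the linking radius only merges components", {
  set.seed(17)
  x <- runif(120, 0, 1500); y <- runif(120, 0, 1500)
  pts <- leukocyte_points(x, y, 2.25)
  prev <- Inf
  for (r in c(20, 40, 80, 160, 320)) {
    ncomp <- length(detect_foci(pts, r, min_cells = 1)$foci_members)
    expect_lte(ncomp, prev)
    prev <- ncomp
  }
})

test_that("two well-separated clusters are counted separately", {
  set.seed(30)
  make_clump <- function(cx, cy, n) {
    ang <- runif(n, 0, 2 * pi); rad <- 20 * sqrt(runif(n))
    cbind(cx + rad * cos(ang), cy + rad * sin(ang))
  }
  a <- make_clump(100, 100, 30); b <- make_clump(600, 100, 30)
  pts <- leukocyte_points(c(a[, 1], b[, 1]), c(a[, 2], b[, 2]), 1)
  det <- detect_foci(pts)
  expect_equal(det$n_foci, 2)
  expect_equal(sort(lengths(det$foci_members)), c(30, 30))
})

test_that("density arithmetic follows n * 20 / area", {
  expect_equal(foci_density(12, 60), 4)
  expect_equal(foci_density(0, 17.3), 0)
  expect_equal(foci_density(3, 20), 3)
  expect_error(foci_density(2, 0), "invalid input")
  expect_error(foci_density(-1, 5), "invalid input")
  det <- detect_foci(leukocyte_points(numeric(0), numeric(0), 10))
  expect_equal(det$foci_per_20mm2, 0)
})
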