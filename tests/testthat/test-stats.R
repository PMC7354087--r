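test_that("exact Mann-Whitney p equals literal enumeration on all small designs", {
  set.seed(42)
  for (n1 in 2:4) for (n2 in 2:4) {
    for (rep in 1:3) {
      x <- round(rnorm(n1), 1)   # rounding induces occasional ties
      y <- round(rnorm(n2), 1)
      res <- mann_whitney_exact(x, y)
      expect_true(res$exact)
      expect_equal(res$p_two_sided, oracle_mw_p(x, y),
                   info = sprintf("n1=%d n2=%d rep=%d", n1, n2, rep))
    }
  }
})

test_that("Mann-Whitney agrees with wilcox.test on untied data and is symmetric", {
  set.seed(7)
  for (rep in 1:5) {
    x <- rnorm(6); y <- rnorm(5)
    res <- mann_whitney_exact(x, y)
    expect_equal(res$p_two_sided,
                 wilcox.test(x, y, exact = TRUE)$p.value)
    expect_equal(res$p_two_sided, mann_whitney_exact(y, x)$p_two_sided)
  }
})

test_that("complete separation gives the minimal p = 2/choose(n1+n2, n1)", {
  for (n1 in 2:6) for (n2 in 2:6) {
    x <- seq_len(n1); y <- n1 + seq_len(n2)
    expect_equal(mann_whitney_exact(x, y)$p_two_sided,
                 2 / choose(n1 + n2, n1))
  }
})

test_that("Mann-Whitney handles degenerate and large-sample inputs", {
  res <- mann_whitney_exact(rep(3, 4), rep(3, 5))
  expect_true(res$degenerate)
  expect_equal(res$p_two_sided, 1)
  set.seed(1)
  big <- mann_whitney_exact(rnorm(15), rnorm(15))
  expect_false(big$exact)
  expect_gt(big$p_two_sided, 0)
  expect_lte(big$p_two_sided, 1)
})

test_that("Kruskal-Wallis H matches the direct rank formula and kruskal.test", {
  # ranks (1,2), (3,4), (5,6): H = 12/(N(N+1)) * sum n_i (Rbar_i - (N+1)/2)^2
  res <- kruskal_wallis(list(c(1, 2), c(3, 4), c(5, 6)))
  expect_equal(res$statistic, 32 / 7)
  set.seed(3)
  g <- list(rnorm(5), rnorm(4), round(rnorm(5), 1))
  res2 <- kruskal_wallis(g)
  ref <- kruskal.test(unlist(g), rep(1:3, lengths(g)))
  expect_equal(res2$statistic, unname(ref$statistic))
  expect_equal(res2$p_two_sided, ref$p.value)
  expect_error(kruskal_wallis(list(1:3)), "invalid design")
})

test_that("Kruskal-Wallis degenerate and exact paths behave", {
  res <- kruskal_wallis(list(c(1, 1), c(1, 1), c(1, 1)))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_two_sided, 1)
  # exact enumeration: p is the tail of the permutation distribution
  ex <- kruskal_wallis(list(c(1, 2), c(3, 4), c(5, 6)), exact = TRUE)
  expect_true(ex$exact)
  expect_true(ex$p_two_sided > 0 && ex$p_two_sided <= 1)
  # separation at these sizes is the most extreme table: smallest possible p
  shuffled <- kruskal_wallis(list(c(1, 6), c(2, 5), c(3, 4)), exact = TRUE)
  expect_gt(shuffled$p_two_sided, ex$p_two_sided)
})

test_that("exact signed-rank p equals the 2^n sign-flip oracle", {
  set.seed(11)
  for (n in c(4, 6, 8)) {
    for (rep in 1:3) {
      d <- round(rnorm(n), 1)
      d <- d[d != 0]
      if (length(d) == 0) next
      res <- wilcoxon_signed_rank_exact(d)
      expect_true(res$exact)
      expect_equal(res$p_two_sided, oracle_wsr_p(d),
                   info = sprintf("n=%d rep=%d", n, rep))
    }
  }
})

test_that("signed-rank handles all-positive, symmetric, and zero cases", {
  expect_equal(wilcoxon_signed_rank_exact(c(1, 2, 3, 4, 5))$p_two_sided,
               2 / 32)
  expect_equal(wilcoxon_signed_rank_exact(c(2, -2))$p_two_sided, 1)
  res0 <- wilcoxon_signed_rank_exact(c(0, 0, 0))
  expect_true(res0$degenerate)
  expect_equal(res0$p_two_sided, 1)
  expect_equal(res0$n_zero_dropped, 3)
})

test_that("Spearman rho uses midranks and the exact permutation p", {
  expect_equal(spearman(c(1, 2, 2, 4), c(10, 20, 20, 40))$rho, 1)
  res <- spearman(1:4, c(5, 8, 9, 12))
  expect_equal(res$rho, 1)
  expect_equal(res$p_two_sided, 2 / 24)       # all 24 permutations enumerated
  dec <- spearman(1:5, c(9, 7, 5, 3, 1))
  expect_equal(dec$rho, -1)
  # antisymmetry under sign flip of y
  set.seed(5)
  x <- rnorm(7); y <- rnorm(7)
  expect_equal(spearman(x, -y)$rho, -spearman(x, y)$rho)
  expect_equal(spearman(x, -y)$p_two_sided, spearman(x, y)$p_two_sided)
})

test_that("Spearman flags zero-variance input and approximates at larger n", {
  res <- spearman(rep(1, 5), 1:5)
  expect_true(res$undefined)
  set.seed(9)
  x <- rnorm(20); y <- x + rnorm(20)
  res2 <- spearman(x, y)
  expect_false(res2$exact)
  ref <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  expect_equal(res2$rho, unname(ref$estimate))
  expect_equal(res2$p_two_sided, ref$p.value, tolerance = 1e-6)
})

test_that("the exact 5v5 test rejects at exactly 8/252 under the null, by enumeration", {
  # with continuous data the p-value depends only on which ranks fall in
  # group 1, uniform over all C(10,5) assignments; the achievable level
  # closest to .05 from below is 2 * 4/252
  sets <- utils::combn(10, 5)
  ps <- apply(sets, 2L, function(idx)
    mann_whitney_exact(idx, setdiff(1:10, idx))$p_two_sided)
  expect_equal(mean(ps <= 0.05), 8 / 252)
  expect_equal(min(ps), 2 / 252)
})

test_that("group summaries use median-and-range and fold changes divide medians", {
  s <- summarize_group(c(4, 1, 3, 2))
  expect_equal(s$median, 2.5)                # midpoint of middle two
  expect_equal(c(s$min, s$max, s$n), c(1, 4, 4))
  expect_equal(fold_change(10.98, 1.1)$fold_2dp, 9.98)
  expect_equal(fold_change(5.147, 1.1)$fold_2dp, 4.68)
  expect_equal(round(fold_change(5.147, 1.1)$fold, 1), 4.7)
  expect_equal(round(fold_change(10.98, 5.147)$fold, 2), 2.13)
  expect_error(fold_change(3, 0), "invalid reference")
})
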