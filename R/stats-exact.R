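# Exact small-sample nonparametric tests.
#
# All exact paths enumerate the full permutation reference set, conditioning on
# the observed (midrank) tie pattern, and define the two-sided p-value as
# min(1, 2 * smaller one-sided tail) -- the convention under which complete
# separation at n1 = n2 = 5 gives p = 2/252 = .0079.

# cache for combn() enumerations reused across many small exact tests
.enum_cache <- new.env(parent = emptyenv())

.cached_combn <- function(n, k) {
  key <- paste0(n, ":", k)
  cmb <- .enum_cache[[key]]
  if (is.null(cmb)) {
    cmb <- utils::combn(n, k)
    .enum_cache[[key]] <- cmb
  }
  cmb
}

.rank_test_result <- function(method, statistic, p, exact, n_per_group,
                              degenerate = FALSE, extra = list()) {
  stopifnot(p > 0, p <= 1)
  out <- c(list(method = method, statistic = statistic, p_two_sided = p,
                exact = exact, n_per_group = n_per_group,
                degenerate = degenerate), extra)
  class(out) <- "rank_test"
  out
}

#' @export
print.rank_test <- function(x, ...) {
  cat(sprintf("%s test (%s)\n", x$method,
              if (x$exact) "exact enumeration" else "large-sample approximation"))
  cat(sprintf("  statistic = %g, two-sided p = %.4g\n", x$statistic, x$p_two_sided))
  cat(sprintf("  n = %s\n", paste(x$n_per_group, collapse = " vs ")))
  if (isTRUE(x$degenerate)) cat("  (degenerate input: no separation possible)\n")
  invisible(x)
}

#' Exact Mann-Whitney U test
#'
#' Two-sample rank test with the exact two-sided p-value obtained by full
#' enumeration of all `choose(n1 + n2, n1)` assignments of the pooled midranks
#' whenever the total sample size is at most `exact_limit`. Ties are handled by
#' midranks and the enumeration conditions on the observed tie pattern. The
#' two-sided p-value is `min(1, 2 * min(P(U <= u), P(U >= u)))`, matching the
#' exact output of common biostatistics software: complete separation gives
#' p = 2 / choose(n1 + n2, n1). Beyond `exact_limit` a tie-corrected normal
#' approximation is used.
#'
#' @param x,y Numeric vectors, one per group (both non-empty).
#' @param exact_limit Maximum total sample size for full enumeration.
#' @return A `rank_test` object with elements `statistic` (U of the first
#'   group), `p_two_sided`, `exact`, `n_per_group` and `degenerate`.
#' @examples
#' mann_whitney_exact(1:5, 6:10)$p_two_sided   # 2/252 = 0.0079
#' mann_whitney_exact(1:4, 5:8)$p_two_sided    # 2/70  = 0.0286
#' @export
mann_whitney_exact <- function(x, y, exact_limit = 20L) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 1L || length(y) < 1L) stop("both groups must be non-empty")
  if (anyNA(c(x, y))) stop("missing values are not supported")
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- rank(c(x, y))
  U1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2

  if (length(unique(c(x, y))) == 1L) {
    return(.rank_test_result("mann_whitney", U1, 1, exact = TRUE,
                             n_per_group = c(n1, n2), degenerate = TRUE))
  }

  eps <- 1e-9
  if (N <= exact_limit) {
    cmb <- .cached_combn(N, n1)
    Us <- colSums(matrix(r[cmb], nrow = n1)) - n1 * (n1 + 1) / 2
    p_le <- mean(Us <= U1 + eps)
    p_ge <- mean(Us >= U1 - eps)
    p <- min(1, 2 * min(p_le, p_ge))
    exact <- TRUE
  } else {
    ties <- table(r)
    mu <- n1 * n2 / 2
    sig2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    z <- (U1 - mu) / sqrt(sig2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    exact <- FALSE
  }
  .rank_test_result("mann_whitney", U1, p, exact, c(n1, n2))
}

#' Kruskal-Wallis rank test
#'
#' H statistic with tie correction and a chi-square reference distribution
#' (df = k - 1). For very small designs (`N <= 10` and `exact = TRUE`) the
#' p-value is instead obtained by full enumeration of all distinct assignments
#' of the pooled midranks to the groups.
#'
#' @param groups List of (at least two) non-empty numeric vectors.
#' @param exact Use exact enumeration (only honoured for total n <= 10).
#' @return A `rank_test` object; `statistic` is tie-corrected H.
#' @export
kruskal_wallis <- function(groups, exact = FALSE) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("invalid design: need at least two groups")
  if (any(lengths(groups) == 0L)) stop("invalid design: empty group")
  k <- length(groups)
  v <- unlist(groups, use.names = FALSE)
  if (anyNA(v)) stop("missing values are not supported")
  N <- length(v)
  g <- rep.int(seq_len(k), lengths(groups))
  r <- rank(v)

  H_of <- function(rr) {
    Rbar <- tapply(rr, g, mean)
    12 / (N * (N + 1)) * sum(lengths(groups) * (Rbar - (N + 1) / 2)^2)
  }
  ties <- table(r)
  tiecorr <- 1 - sum(ties^3 - ties) / (N^3 - N)
  if (tiecorr == 0) {  # all values identical
    return(.rank_test_result("kruskal_wallis", 0, 1, exact = TRUE,
                             n_per_group = lengths(groups), degenerate = TRUE))
  }
  H <- H_of(r) / tiecorr

  if (exact && N <= 10L) {
    perms <- .group_assignments(N, lengths(groups))
    Hs <- apply(perms, 1L, function(idx) H_of(r[idx]) / tiecorr)
    p <- mean(Hs >= H - 1e-9)
    is_exact <- TRUE
  } else {
    p <- stats::pchisq(H, df = k - 1, lower.tail = FALSE)
    is_exact <- FALSE
  }
  .rank_test_result("kruskal_wallis", H, max(p, .Machine$double.xmin),
                    is_exact, lengths(groups))
}

# all distinct ways to deal N items into ordered groups of given sizes;
# rows are index permutations (group 1 first, then group 2, ...)
.group_assignments <- function(N, sizes) {
  rec <- function(avail, sizes) {
    if (length(sizes) == 0L) return(matrix(integer(0), nrow = 1L))
    picks <- utils::combn(length(avail), sizes[1L])
    out <- vector("list", ncol(picks))
    for (j in seq_len(ncol(picks))) {
      sel <- picks[, j]
      rest <- rec(avail[-sel], sizes[-1L])
      out[[j]] <- cbind(matrix(rep(avail[sel], each = nrow(rest)),
                               nrow = nrow(rest)), rest)
    }
    do.call(rbind, out)
  }
  rec(seq_len(N), sizes)
}

#' Exact Wilcoxon signed-rank test
#'
#' Paired-difference rank test. Zero differences are dropped (their count is
#' reported); the remaining absolute differences are midranked and the null
#' distribution of the positive-rank sum W over all 2^n sign patterns is
#' computed exactly (by convolution over the scaled rank weights, equivalent to
#' literal enumeration) for n <= `exact_limit`, with a tie-corrected normal
#' approximation beyond.
#'
#' @param diffs Numeric vector of paired differences.
#' @param exact_limit Maximum number of non-zero differences for the exact path.
#' @return A `rank_test` object; `statistic` is W (positive-rank sum);
#'   extra field `n_zero_dropped`.
#' @export
wilcoxon_signed_rank_exact <- function(diffs, exact_limit = 20L) {
  d <- as.numeric(diffs)
  if (anyNA(d)) stop("missing values are not supported")
  nz <- d[d != 0]
  n_zero <- length(d) - length(nz)
  n <- length(nz)
  if (n == 0L) {
    return(.rank_test_result("wilcoxon_signed_rank", 0, 1, exact = TRUE, n,
                             degenerate = TRUE,
                             extra = list(n_zero_dropped = n_zero)))
  }
  r <- rank(abs(nz))
  W <- sum(r[nz > 0])

  if (n <= exact_limit) {
    # midranks are multiples of 1/2: work on integer weights 2*r
    w <- as.integer(round(2 * r))
    total <- sum(w)
    cnt <- numeric(total + 1L)   # cnt[s+1] = #sign patterns with sum(2W) = s
    cnt[1L] <- 1
    for (wi in w) {
      shifted <- c(numeric(wi), cnt[seq_len(total + 1L - wi)])
      cnt <- cnt + shifted
    }
    s_obs <- round(2 * W)
    p_le <- sum(cnt[seq_len(s_obs + 1L)]) / 2^n
    p_ge <- sum(cnt[(s_obs + 1L):(total + 1L)]) / 2^n
    p <- min(1, 2 * min(p_le, p_ge))
    exact <- TRUE
  } else {
    ties <- table(r)
    mu <- n * (n + 1) / 4
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (W - mu) / sqrt(sig2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    exact <- FALSE
  }
  .rank_test_result("wilcoxon_signed_rank", W, p, exact, n,
                    extra = list(n_zero_dropped = n_zero))
}

#' Spearman rank-order correlation
#'
#' rho is the Pearson correlation of midranks. For n <= `exact_limit` the
#' two-sided p-value is exact: the proportion of all n! permutations of one
#' rank vector with |rho| at least the observed |rho|. Beyond that a
#' t-approximation with df = n - 2 is used.
#'
#' @param x,y Numeric vectors of equal length, n >= 3.
#' @param exact_limit Maximum n for exact permutation enumeration.
#' @return List of class `spearman_cor` with `rho`, `p_two_sided`, `n`,
#'   `exact`, and `undefined` (TRUE when either variable has zero variance).
#' @export
spearman <- function(x, y, exact_limit = 9L) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3L) stop("need n >= 3")
  if (anyNA(x) || anyNA(y)) stop("missing values are not supported")
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    out <- list(rho = NA_real_, p_two_sided = NA_real_, n = n,
                exact = FALSE, undefined = TRUE)
    class(out) <- "spearman_cor"
    return(out)
  }
  rho <- stats::cor(rx, ry)

  if (n <= exact_limit) {
    perms <- .all_perms(n)
    # rho is affine in S = sum(rx * ry[perm]); compare |rho| directly
    rxc <- rx - mean(rx); ryc <- ry - mean(ry)
    denom <- sqrt(sum(rxc^2) * sum(ryc^2))
    rhos <- as.vector(matrix(ryc[perms], nrow = nrow(perms)) %*% rxc) / denom
    p <- mean(abs(rhos) >= abs(rho) - 1e-9)
    exact <- TRUE
  } else {
    tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- min(1, 2 * stats::pt(-abs(tstat), df = n - 2))
    p <- max(p, .Machine$double.xmin)
    exact <- FALSE
  }
  out <- list(rho = rho, p_two_sided = p, n = n, exact = exact,
              undefined = FALSE)
  class(out) <- "spearman_cor"
  out
}

#' @export
print.spearman_cor <- function(x, ...) {
  if (isTRUE(x$undefined)) {
    cat("Spearman correlation undefined (zero variance)\n")
  } else {
    cat(sprintf("Spearman rho = %.4f, two-sided p = %.4g (n = %d, %s)\n",
                x$rho, x$p_two_sided, x$n,
                if (x$exact) "exact" else "t-approximation"))
  }
  invisible(x)
}

.all_perms <- function(n) {
  key <- paste0("perm:", n)
  p <- .enum_cache[[key]]
  if (is.null(p)) {
    rec <- function(v) {
      if (length(v) == 1L) return(matrix(v, 1L))
      do.call(rbind, lapply(seq_along(v), function(i) {
        cbind(v[i], rec(v[-i]))
      }))
    }
    p <- rec(seq_len(n))
    .enum_cache[[key]] <- p
  }
  p
}

#' Median-and-range group summary
#'
#' @param values Non-empty numeric vector.
#' @return List with `median` (midpoint-of-middle-two convention for even n),
#'   `min`, `max`, `n`.
#' @export
summarize_group <- function(values) {
  v <- as.numeric(values)
  if (length(v) == 0L || anyNA(v)) stop("need non-empty values without NA")
  list(median = stats::median(v), min = min(v), max = max(v), n = length(v))
}

#' Fold change between two medians
#'
#' @param a_median,b_median Numeric; `b_median` is the reference and must be
#'   non-zero.
#' @return List with `fold` (raw ratio a/b) and `fold_2dp` (rounded to two
#'   decimals, the conventional reporting precision).
#' @export
fold_change <- function(a_median, b_median) {
  if (!is.finite(b_median) || b_median == 0)
    stop("invalid reference: zero or non-finite median")
  f <- a_median / b_median
  list(fold = f, fold_2dp = round(f, 2))
}
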