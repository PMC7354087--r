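# Independent oracles, deliberately written as naive scans/enumerations so
# they share no code path with the package implementation.

# pixel-by-pixel run-length scan of air chords along one raster line
oracle_line_chords <- function(air_vec, pixel_size_um, min_chord_um) {
  out <- numeric(0)
  run_start <- NA_integer_
  for (i in seq_along(air_vec)) {
    if (air_vec[i] && is.na(run_start)) run_start <- i
    if (!air_vec[i] && !is.na(run_start)) {
      if (run_start > 1L) {                 # run did not touch the left border
        len <- (i - run_start) * pixel_size_um
        if (len >= min_chord_um) out <- c(out, len)
      }
      run_start <- NA_integer_
    }
  }
  # a run still open at the right border is clipped: discarded
  out
}

# every row and every column of the mask (1 px spacing), both orientations
oracle_all_chords <- function(mask, pixel_size_um, min_chord_um = 10) {
  out <- numeric(0)
  for (i in seq_len(nrow(mask)))
    out <- c(out, oracle_line_chords(!mask[i, ], pixel_size_um, min_chord_um))
  for (j in seq_len(ncol(mask)))
    out <- c(out, oracle_line_chords(!mask[, j], pixel_size_um, min_chord_um))
  out
}

# O(n^2) all-pairs union-find, the reference for single-linkage components
oracle_components <- function(x, y, r) {
  n <- length(x)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      if ((x[i] - x[j])^2 + (y[i] - y[j])^2 <= r^2 && comp[i] != comp[j]) {
        comp[comp == comp[j]] <- comp[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  match(comp, unique(comp))
}

# literal enumeration over every assignment of the pooled values to group 1
oracle_mw_p <- function(x, y) {
  n1 <- length(x); N <- n1 + length(y)
  r <- rank(c(x, y))
  U_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  sets <- utils::combn(N, n1)
  Us <- apply(sets, 2L, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  min(1, 2 * min(mean(Us <= U_obs + 1e-9), mean(Us >= U_obs - 1e-9)))
}

# literal 2^n sign-flip enumeration for the signed-rank test
oracle_wsr_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  Ws <- apply(signs, 1L, function(s) sum(r[s]))
  min(1, 2 * min(mean(Ws <= W_obs + 1e-9), mean(Ws >= W_obs - 1e-9)))
}

make_section <- function(mask, pixel_size_um = 1, ...) {
  histology_section(mask, pixel_size_um, ...)
}

random_mask <- function(nr, nc, p_tissue = 0.4, seed = 1) {
  set.seed(seed)
  matrix(runif(nr * nc) < p_tissue, nr, nc)
}
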