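# Synthetic alveolar histology.
#
# Two phantom morphologies:
#  * parallel_septa -- vertical tissue walls on a fixed period; every interior
#    horizontal air chord equals period - septum exactly, giving an analytic
#    ground truth.
#  * voronoi_foam -- Voronoi tessellation of a jittered-lattice point process;
#    the boundary band between the two nearest seeds (width ~ septum_um) is
#    tissue. Airspace enlargement is modelled by deleting a fraction of the
#    shared walls, mimicking septal destruction; the deletion order is a fixed
#    seeded permutation so larger fractions remove strict supersets of walls
#    and the true mean chord is monotone in the fraction at fixed seed.
#
# The foam's true mean air-chord length has no closed form; it is established
# by exhaustive chord measurement at 1 px line spacing over the entire mask.

#' Generate a synthetic alveolar tissue section
#'
#' @param morphology `"voronoi_foam"` or `"parallel_septa"`.
#' @param period_um Characteristic cell size (lattice period), um.
#' @param septum_um Septal wall thickness, um; must be below `period_um`.
#' @param emphysema_fraction Fraction in `[0, 1]` of shared foam walls removed
#'   (ignored for `parallel_septa`).
#' @param size_px Mask size, `c(rows, cols)` or a single edge length.
#' @param pixel_size_um Physical pixel size, um.
#' @param seed Integer seed; identical arguments and seed give a bit-identical
#'   mask.
#' @param min_chord_um Minimum chord used when establishing the foam's
#'   exhaustive ground truth (default 10, matching the measurement convention).
#' @return List with `section` (a [histology_section()]) and `truth` (list:
#'   `true_mean_chord_um`, `morphology`, `emphysema_fraction`, `seed`, ...).
#' @examples
#' ph <- generate_alveolar_section("parallel_septa", period_um = 50,
#'                                 septum_um = 10, size_px = 200,
#'                                 pixel_size_um = 1, seed = 1)
#' ph$truth$true_mean_chord_um  # 40
#' @export
generate_alveolar_section <- function(morphology = c("voronoi_foam",
                                                     "parallel_septa"),
                                      period_um = 46, septum_um = 7,
                                      emphysema_fraction = 0,
                                      size_px = c(900L, 900L),
                                      pixel_size_um = 2, seed = 1L,
                                      min_chord_um = 10) {
  morphology <- match.arg(morphology)
  if (!(period_um > septum_um && septum_um > 0))
    stop("need period_um > septum_um > 0")
  if (pixel_size_um <= 0) stop("pixel_size_um must be positive")
  if (emphysema_fraction < 0 || emphysema_fraction > 1)
    stop("emphysema_fraction must lie in [0, 1]")
  if (length(size_px) == 1L) size_px <- c(size_px, size_px)
  size_px <- as.integer(size_px)
  period_px <- period_um / pixel_size_um
  if (period_px < 2) stop("degenerate geometry: period smaller than 2 pixels")

  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))

  mask <- switch(morphology,
    parallel_septa = .septa_mask(size_px, period_um, septum_um, pixel_size_um),
    voronoi_foam = .foam_mask(size_px, period_um, septum_um, pixel_size_um,
                              emphysema_fraction))

  section <- histology_section(mask, pixel_size_um,
                               section_id = sprintf("synth-%d", seed))
  true_chord <- if (morphology == "parallel_septa") {
    period_um - septum_um
  } else {
    exhaustive_mean_chord(section, min_chord_um = min_chord_um)
  }
  list(section = section,
       truth = list(true_mean_chord_um = true_chord,
                    morphology = morphology,
                    period_um = period_um, septum_um = septum_um,
                    emphysema_fraction = emphysema_fraction,
                    pixel_size_um = pixel_size_um, seed = seed))
}

.septa_mask <- function(size_px, period_um, septum_um, pixel_size_um) {
  pos_um <- (seq_len(size_px[2L]) - 1L) * pixel_size_um
  tissue_col <- (pos_um %% period_um) < septum_um
  matrix(tissue_col, nrow = size_px[1L], ncol = size_px[2L], byrow = TRUE)
}

.foam_mask <- function(size_px, period_um, septum_um, pixel_size_um,
                       emphysema_fraction) {
  nr <- size_px[1L]; nc <- size_px[2L]
  p <- period_um / pixel_size_um          # lattice period in px
  pad <- 3L                               # lattice cells beyond each border
  nR <- as.integer(ceiling(nr / p)) + 2L * pad
  nC <- as.integer(ceiling(nc / p)) + 2L * pad

  # one seed per lattice cell, jittered; jitter < 0.5 cell keeps the nearest
  # and second-nearest seed of any pixel within a 2-cell neighbourhood
  jx <- matrix(stats::runif(nR * nC, -0.45, 0.45), nR, nC)
  jy <- matrix(stats::runif(nR * nC, -0.45, 0.45), nR, nC)
  SX <- (matrix(seq_len(nR), nR, nC) - pad - 0.5 + jx) * p  # row coordinate
  SY <- (matrix(seq_len(nC), nR, nC, byrow = TRUE) - pad - 0.5 + jy) * p

  px_r <- rep(seq_len(nr) - 0.5, times = nc)
  px_c <- rep(seq_len(nc) - 0.5, each = nr)
  cell_r <- pmin(pmax(as.integer(floor((seq_len(nr) - 0.5) / p)) + 1L + pad,
                      1L + 2L), nR - 2L)
  cell_c <- pmin(pmax(as.integer(floor((seq_len(nc) - 0.5) / p)) + 1L + pad,
                      1L + 2L), nC - 2L)
  Cr <- rep(cell_r, times = nc)
  Cc <- rep(cell_c, each = nr)

  n <- nr * nc
  d1 <- rep(Inf, n); d2 <- rep(Inf, n)
  s1 <- integer(n); s2 <- integer(n)
  for (dR in -2L:2L) {
    for (dC in -2L:2L) {
      idx <- (Cc + dC - 1L) * nR + (Cr + dR)   # linear index into lattice
      dd <- (px_r - SX[idx])^2 + (px_c - SY[idx])^2
      closer <- dd < d1
      second <- !closer & dd < d2
      d2[closer] <- d1[closer]; s2[closer] <- s1[closer]
      d1[closer] <- dd[closer]; s1[closer] <- idx[closer]
      d2[second] <- dd[second]; s2[second] <- idx[second]
    }
  }
  d1 <- sqrt(d1); d2 <- sqrt(d2)

  sept_px <- septum_um / pixel_size_um
  wall <- (d2 - d1) <= sept_px
  if (emphysema_fraction > 0) {
    lo <- pmin(s1, s2); hi <- pmax(s1, s2)
    pair <- lo * (nR * nC + 1) + hi          # unique key per unordered pair
    wall_pairs <- unique(pair[wall])
    # fixed permutation (drawn after the jitters, independent of the fraction)
    # so removal sets are nested across fractions at the same seed
    ord <- sample.int(length(wall_pairs))
    n_remove <- floor(emphysema_fraction * length(wall_pairs))
    if (n_remove > 0L) {
      removed <- wall_pairs[ord[seq_len(n_remove)]]
      wall <- wall & !(pair %in% removed)
    }
  }
  matrix(wall, nr, nc)
}
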