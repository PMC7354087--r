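# Synthetic leukocyte point patterns, micro-CT volumes and T2-weighted slices
# with recorded ground truth.

#' Inject leukocyte foci into a section's coordinate frame
#'
#' Places `n_foci` disjoint circular clusters of cells inside the physical
#' extent of a section, with inter-focus gaps wide enough (six default linking
#' radii beyond the focus diameters) that single-linkage detection at default
#' settings can never merge them, plus a sparse uniform background of isolated
#' cells.
#'
#' @param section A [histology_section()] supplying the physical extent, or a
#'   list with `width_um` and `height_um`.
#' @param n_foci Number of clusters to place (>= 0).
#' @param cells_per_focus Cells per cluster; at least 21 so every injected
#'   focus passes the strict "more than 20 cells" rule.
#' @param focus_radius_um Cluster radius, um.
#' @param background_density_per_mm2 Intensity of the background Poisson
#'   scatter (cells per mm^2); the default is sparse enough that background
#'   cells cannot form spurious foci at default detection settings.
#' @param seed Integer seed.
#' @param min_gap_um Minimum empty gap between focus boundaries (default 150,
#'   six default linking radii).
#' @return List with `points` (a [leukocyte_points()]) and `truth`
#'   (`true_n_foci`, focus centres, `seed`).
#' @export
inject_leukocyte_foci <- function(section, n_foci, cells_per_focus = 25L,
                                  focus_radius_um = 50,
                                  background_density_per_mm2 = 2,
                                  seed = 1L, min_gap_um = 150) {
  if (n_foci < 0) stop("n_foci must be non-negative")
  if (n_foci > 0 && cells_per_focus < 21L)
    stop("cells_per_focus must be at least 21 (the >20-cell focus rule)")
  if (inherits(section, "histology_section")) {
    W <- ncol(section$tissue_mask) * section$pixel_size_um
    H <- nrow(section$tissue_mask) * section$pixel_size_um
    sec_id <- section$section_id; sub_id <- section$subject_id
  } else {
    W <- section$width_um; H <- section$height_um
    sec_id <- if (!is.null(section$section_id)) section$section_id else "S1"
    sub_id <- if (!is.null(section$subject_id)) section$subject_id else "M1"
  }
  area_mm2 <- W * H / 1e6

  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))

  min_sep <- 2 * focus_radius_um + min_gap_um
  centres <- matrix(numeric(0), ncol = 2L)
  tries <- 0L
  max_tries <- 1000L * max(1L, n_foci)
  while (nrow(centres) < n_foci) {
    tries <- tries + 1L
    if (tries > max_tries)
      stop("placement failure: could not fit the requested foci in the section")
    cx <- stats::runif(1, focus_radius_um, W - focus_radius_um)
    cy <- stats::runif(1, focus_radius_um, H - focus_radius_um)
    if (nrow(centres) == 0L ||
        all((centres[, 1L] - cx)^2 + (centres[, 2L] - cy)^2 >= min_sep^2)) {
      centres <- rbind(centres, c(cx, cy))
    }
  }

  # cells accrete onto the growing cluster at 5-20 um from an existing cell,
  # so every focus is single-linkage connected at the default 25 um radius
  # by construction, while staying inside its disc
  xs <- numeric(0); ys <- numeric(0)
  for (k in seq_len(n_foci)) {
    fx <- centres[k, 1L]; fy <- centres[k, 2L]
    for (i in seq_len(cells_per_focus)[-1L]) {
      repeat {
        j <- sample.int(i - 1L, 1L)
        step <- stats::runif(1, 5, 20)
        ang <- stats::runif(1, 0, 2 * pi)
        nx <- fx[j] + step * cos(ang); ny <- fy[j] + step * sin(ang)
        if ((nx - centres[k, 1L])^2 + (ny - centres[k, 2L])^2 <=
            focus_radius_um^2) break
      }
      fx <- c(fx, nx); fy <- c(fy, ny)
    }
    xs <- c(xs, fx); ys <- c(ys, fy)
  }
  n_bg <- stats::rpois(1L, background_density_per_mm2 * area_mm2)
  if (n_bg > 0L) {
    xs <- c(xs, stats::runif(n_bg, 0, W))
    ys <- c(ys, stats::runif(n_bg, 0, H))
  }
  list(points = leukocyte_points(xs, ys, area_mm2, sec_id, sub_id),
       truth = list(true_n_foci = as.integer(n_foci), centres_um = centres,
                    cells_per_focus = cells_per_focus,
                    focus_radius_um = focus_radius_um,
                    background_density_per_mm2 = background_density_per_mm2,
                    seed = seed))
}

#' Generate a raw micro-CT phantom volume
#'
#' The volume holds a lung region, a distilled-water calibration cylinder, an
#' air pocket and a soft-tissue remainder. Raw scanner intensities are an
#' affine transform of true Hounsfield units with a seeded unknown gain in
#' `[0.5, 2]` and offset in `[-200, 200]`, so HU calibration from the water
#' and air regions is a genuine step. Noise is additive Gaussian on the HU
#' scale (applied before the affine map).
#'
#' @param lung_mean_hu True mean HU of the lung region (e.g. -400).
#' @param noise_sd_hu Gaussian noise SD, HU.
#' @param shape Volume dimensions, at least 16 voxels per axis.
#' @param voxel_size_um Isotropic voxel size, um (metadata only).
#' @param seed Integer seed.
#' @return List with `raw` (3-D array of raw intensities), `labels` (integer
#'   array: 1 = lung, 2 = muscle/soft tissue, 4 = water, 5 = air), `voi`
#'   (logical array, the lower-lung volume of interest), and `truth`
#'   (`true_lung_hu`, `gain`, `offset`, `seed`).
#' @export
generate_ct_volume <- function(lung_mean_hu = -400, noise_sd_hu = 0,
                               shape = c(32L, 32L, 32L), voxel_size_um = 18,
                               seed = 1L) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 16L))
    stop("shape must be at least 16 voxels along every axis")
  if (noise_sd_hu < 0) stop("noise_sd_hu must be non-negative")

  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))

  nx <- shape[1L]; ny <- shape[2L]; nz <- shape[3L]
  labels <- array(0L, shape)
  true_hu <- array(40, shape)                      # soft-tissue background

  # lung: centred ellipsoid occupying ~half of each axis
  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2; cz <- (nz + 1) / 2
  ax <- nx * 0.3; ay <- ny * 0.3; az <- nz * 0.3
  X <- slice.index(labels, 1L); Y <- slice.index(labels, 2L)
  Z <- slice.index(labels, 3L)
  lung <- ((X - cx) / ax)^2 + ((Y - cy) / ay)^2 + ((Z - cz) / az)^2 <= 1
  labels[lung] <- 1L
  true_hu[lung] <- lung_mean_hu

  # water cylinder in one corner, air pocket in the opposite corner
  q <- max(3L, nx %/% 6L)
  water <- (X - q)^2 + (Y - q)^2 <= (q - 1)^2 & Z >= 2 & Z <= nz - 1
  water <- water & !lung
  labels[water] <- 4L
  true_hu[water] <- 0
  air <- X >= nx - q & Y >= ny - q & Z >= nz - q
  air <- air & !lung & !water
  labels[air] <- 5L
  true_hu[air] <- -1000
  labels[labels == 0L] <- 2L                        # remainder: soft tissue

  gain <- stats::runif(1, 0.5, 2)
  offset <- stats::runif(1, -200, 200)
  noisy <- true_hu
  if (noise_sd_hu > 0)
    noisy <- noisy + array(stats::rnorm(length(true_hu), 0, noise_sd_hu), shape)
  raw <- gain * noisy + offset

  # the supplied volume of interest: the lower half of the lung region
  # (mirrors restricting analysis to the lower lung)
  voi <- lung & Z <= cz
  list(raw = raw, labels = labels, voi = voi,
       voxel_size_um = voxel_size_um,
       truth = list(true_lung_hu = lung_mean_hu, gain = gain, offset = offset,
                    noise_sd_hu = noise_sd_hu, seed = seed))
}

#' Generate a T2-weighted slice phantom
#'
#' A 2-D intensity image with labelled lung, arm-muscle and kidney regions at
#' stated mean levels plus Gaussian noise. The true lung/muscle intensity
#' ratio is recorded.
#'
#' @param lung_level,muscle_level,kidney_level Region mean intensities;
#'   `muscle_level` must be positive (it is the normaliser).
#' @param noise_sd Gaussian noise SD.
#' @param shape Image dimensions (rows, cols).
#' @param seed Integer seed.
#' @return List with `image` (matrix), `labels` (integer matrix: 1 = lung,
#'   2 = muscle, 3 = kidney, 0 = background) and `truth` (`true_t2_ratio`,
#'   `true_kidney_ratio`, `seed`).
#' @export
generate_mr_slice <- function(lung_level = 300, muscle_level = 250,
                              kidney_level = 280, noise_sd = 0,
                              shape = c(64L, 64L), seed = 1L) {
  if (!is.numeric(muscle_level) || muscle_level <= 0)
    stop("invalid parameter: muscle_level must be positive")
  shape <- as.integer(shape)
  if (length(shape) != 2L || any(shape < 16L))
    stop("shape must be at least 16 pixels along each axis")

  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))

  nr <- shape[1L]; nc <- shape[2L]
  labels <- matrix(0L, nr, nc)
  img <- matrix(100, nr, nc)                       # background level

  R <- row(labels); C <- col(labels)
  lung <- ((R - nr * 0.4) / (nr * 0.22))^2 + ((C - nc * 0.5) / (nc * 0.3))^2 <= 1
  muscle <- R >= nr * 0.75 & R <= nr * 0.9 & C >= nc * 0.1 & C <= nc * 0.35
  kidney <- ((R - nr * 0.75) / (nr * 0.08))^2 +
    ((C - nc * 0.7) / (nc * 0.1))^2 <= 1
  labels[lung] <- 1L; labels[muscle & labels == 0L] <- 2L
  labels[kidney & labels == 0L] <- 3L
  img[labels == 1L] <- lung_level
  img[labels == 2L] <- muscle_level
  img[labels == 3L] <- kidney_level
  if (noise_sd > 0) img <- img + matrix(stats::rnorm(nr * nc, 0, noise_sd),
                                        nr, nc)
  list(image = img, labels = labels,
       truth = list(true_t2_ratio = lung_level / muscle_level,
                    true_kidney_ratio = kidney_level / muscle_level,
                    seed = seed))
}
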