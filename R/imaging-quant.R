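# Micro-CT densitometry and T2-weighted MRI intensity ratios.

#' Calibrate raw CT intensities to Hounsfield units
#'
#' Linear two-point calibration anchored at distilled water (0 HU) and air
#' (-1000 HU): `HU(v) = 1000 * (v - water) / (water - air)`, then clamped to
#' the reconstruction range `[-1000, 1000]`. The mapping is invariant to any
#' affine distortion of the raw scale provided the anchors are measured on the
#' same distorted scale.
#'
#' @param raw_volume Numeric array of raw scanner intensities.
#' @param water_raw_mean,air_raw_mean Mean raw intensity of the water and air
#'   calibration regions; must differ.
#' @param clamp_range Reconstruction clamp, default `c(-1000, 1000)`.
#' @return A `calibrated_volume`: `voxels` (HU array), `calibration`,
#'   `clamp_range`.
#' @export
calibrate_hu <- function(raw_volume, water_raw_mean, air_raw_mean,
                         clamp_range = c(-1000, 1000)) {
  if (!is.numeric(water_raw_mean) || !is.numeric(air_raw_mean) ||
      water_raw_mean == air_raw_mean)
    stop("degenerate calibration: water and air references are equal")
  hu <- 1000 * (raw_volume - water_raw_mean) / (water_raw_mean - air_raw_mean)
  hu <- pmin(pmax(hu, clamp_range[1L]), clamp_range[2L])
  structure(list(voxels = hu,
                 calibration = list(water_raw_mean = water_raw_mean,
                                    air_raw_mean = air_raw_mean),
                 clamp_range = clamp_range),
            class = "calibrated_volume")
}

#' Threshold a calibrated volume to lung-like voxels
#'
#' Keeps voxels whose HU lies inside the closed lung window, excluding bone
#' and soft tissue above and trachea-like pure air below.
#'
#' @param volume A [calibrate_hu()] result (or HU array).
#' @param lung_window Closed HU window, default `c(-900, -100)`.
#' @return Logical array the shape of the volume.
#' @export
segment_lung <- function(volume, lung_window = c(-900, -100)) {
  hu <- if (inherits(volume, "calibrated_volume")) volume$voxels else volume
  if (length(lung_window) != 2L || lung_window[1L] > lung_window[2L])
    stop("invalid lung window")
  keep <- hu >= lung_window[1L] & hu <= lung_window[2L]
  if (!any(keep)) warning("empty lung segmentation: no voxel inside the window")
  keep
}

#' Mean HU over a volume of interest
#'
#' Arithmetic mean of calibrated HU over the intersection of the supplied VOI
#' with an optional lung-window mask.
#'
#' @param volume A [calibrate_hu()] result (or HU array).
#' @param voi Logical array, the volume of interest; non-empty, same shape.
#' @param lung_mask Optional logical array (e.g. from [segment_lung()]);
#'   `NULL` uses the full VOI.
#' @return A `ct_result`: `mean_hu`, `n_voxels_used`, `lung_window` (range of
#'   the voxels actually used).
#' @export
mean_hu <- function(volume, voi, lung_mask = NULL) {
  hu <- if (inherits(volume, "calibrated_volume")) volume$voxels else volume
  if (!identical(dim(voi), dim(hu))) stop("VOI shape does not match volume")
  sel <- voi
  if (!is.null(lung_mask)) {
    if (!identical(dim(lung_mask), dim(hu)))
      stop("lung mask shape does not match volume")
    sel <- sel & lung_mask
  }
  n <- sum(sel)
  if (n == 0L) stop("no lung in VOI: empty intersection")
  vals <- hu[sel]
  structure(list(mean_hu = mean(vals), n_voxels_used = n,
                 lung_window = range(vals)),
            class = "ct_result")
}

#' @export
print.ct_result <- function(x, ...) {
  cat(sprintf("mean lung density %.1f HU over %d voxels (range %.1f to %.1f)\n",
              x$mean_hu, x$n_voxels_used, x$lung_window[1L], x$lung_window[2L]))
  invisible(x)
}

#' T2-weighted intensity ratios
#'
#' Normalises mean lung (and kidney, when present) intensity by mean arm-muscle
#' intensity in the same slice; the gain of the scanner cancels exactly.
#'
#' @param slice List with `image` (matrix) and `labels` (integer matrix using
#'   codes 1 = lung, 2 = muscle, 3 = kidney), e.g. [generate_mr_slice()]
#'   output.
#' @return A `t2_ratio_result`: `ratio_lung`, `ratio_kidney` (`NA` when no
#'   kidney ROI), region means.
#' @export
t2_ratio <- function(slice) {
  img <- slice$image; lab <- slice$labels
  if (is.null(img) || is.null(lab) || !identical(dim(img), dim(lab)))
    stop("slice must carry an image and matching labels")
  if (!any(lab == 2L)) stop("normalization error: empty muscle ROI")
  if (!any(lab == 1L)) stop("empty lung ROI")
  m_lung <- mean(img[lab == 1L])
  m_musc <- mean(img[lab == 2L])
  m_kid <- if (any(lab == 3L)) mean(img[lab == 3L]) else NA_real_
  structure(list(ratio_lung = m_lung / m_musc,
                 ratio_kidney = m_kid / m_musc,
                 mean_lung = m_lung, mean_muscle = m_musc,
                 mean_kidney = m_kid),
            class = "t2_ratio_result")
}

#' @export
print.t2_ratio_result <- function(x, ...) {
  cat(sprintf("T2 lung/muscle ratio %.3f", x$ratio_lung))
  if (!is.na(x$ratio_kidney))
    cat(sprintf(", kidney/muscle ratio %.3f", x$ratio_kidney))
  cat("\n")
  invisible(x)
}

#' Percentage change from a baseline timepoint
#'
#' `100 * (v_t - v_baseline) / v_baseline` for each timepoint. Applied to
#' signed series (such as lung HU, which is negative) the computation uses the
#' raw signed values: a change from -357 to -399.1 HU is +11.79% (the signed
#' value moved further from zero by that fraction of its baseline magnitude,
#' with the sign of the baseline cancelling).
#'
#' @param values Numeric vector of a subject's measurements over time.
#' @param weeks Matching vector of week indices.
#' @param baseline_week The reference week (default 0); its value must be
#'   present and non-zero.
#' @return Named numeric vector of percentages, one per week (including 0 at
#'   the baseline), or `NULL` with a warning when the baseline is missing.
#' @export
percent_change <- function(values, weeks, baseline_week = 0) {
  if (length(values) != length(weeks)) stop("values and weeks differ in length")
  i0 <- which(weeks == baseline_week)
  if (length(i0) != 1L || is.na(values[i0])) {
    warning("baseline week missing: subject skipped")
    return(NULL)
  }
  v0 <- values[i0]
  if (v0 == 0) stop("zero baseline value")
  out <- 100 * (values - v0) / v0
  names(out) <- as.character(weeks)
  out
}
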