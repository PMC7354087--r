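# Mean linear intercept (Lm) by grid-overlay chord measurement.
#
# Lm is estimated from air chords: contiguous runs of airspace along parallel
# test lines laid over a calibrated binary tissue mask. Runs clipped by the
# field border are discarded (right-censored lengths bias Lm downward), as are
# runs shorter than a minimum chord length (10 um by convention). Horizontal
# and vertical line sets are pooled to control rotation bias, and the subject
# value is a hierarchical unweighted mean: chords -> field mean -> section
# mean -> subject Lm.

#' Construct a histology section
#'
#' @param tissue_mask Logical matrix, `TRUE` = tissue, `FALSE` = airspace.
#' @param pixel_size_um Physical pixel size in micrometres (> 0).
#' @param exclusion_mask Optional logical matrix of the same shape; `TRUE`
#'   marks pixels belonging to bronchioles, vessels wider than 50 um, or other
#'   non-airway structure. Fields touching it are rejected. Defaults to none.
#' @param section_id,subject_id Identifiers carried through to results.
#' @return A `histology_section` object.
#' @export
histology_section <- function(tissue_mask, pixel_size_um,
                              exclusion_mask = NULL,
                              section_id = "S1", subject_id = "M1") {
  if (is.numeric(tissue_mask)) tissue_mask <- tissue_mask > 0
  stopifnot(is.logical(tissue_mask), is.matrix(tissue_mask))
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      pixel_size_um <= 0)
    stop("pixel_size_um must be a single positive number")
  if (is.null(exclusion_mask)) {
    exclusion_mask <- matrix(FALSE, nrow(tissue_mask), ncol(tissue_mask))
  }
  if (is.numeric(exclusion_mask)) exclusion_mask <- exclusion_mask > 0
  if (!identical(dim(exclusion_mask), dim(tissue_mask)))
    stop("exclusion_mask must match tissue_mask in shape")
  structure(list(tissue_mask = tissue_mask,
                 exclusion_mask = exclusion_mask,
                 pixel_size_um = pixel_size_um,
                 section_id = section_id, subject_id = subject_id),
            class = "histology_section")
}

#' @export
print.histology_section <- function(x, ...) {
  cat(sprintf("histology_section %s/%s: %d x %d px @ %g um/px (%.2f x %.2f mm)\n",
              x$subject_id, x$section_id,
              nrow(x$tissue_mask), ncol(x$tissue_mask), x$pixel_size_um,
              nrow(x$tissue_mask) * x$pixel_size_um / 1000,
              ncol(x$tissue_mask) * x$pixel_size_um / 1000))
  cat(sprintf("  tissue fraction %.3f, excluded fraction %.3f\n",
              mean(x$tissue_mask), mean(x$exclusion_mask)))
  invisible(x)
}

#' Select non-overlapping measurement fields
#'
#' Systematic uniform placement: candidate fields tile the section on a regular
#' lattice with stride equal to the field size and a single seeded random
#' offset; candidates that intersect the exclusion mask are dropped and the
#' requested number of fields is taken spread evenly over the survivors.
#'
#' @param section A [histology_section()].
#' @param n_fields Number of fields requested (default 5).
#' @param field_size_px Field edge length in pixels.
#' @param seed Integer seed for the lattice offset.
#' @return A data frame with one row per field: `row0`, `col0` (1-based top
#'   left), `size_px`, `field_id`. Fewer rows than `n_fields` (with a warning)
#'   when the section cannot host that many clean fields; an error when no
#'   usable field exists.
#' @export
select_fields <- function(section, n_fields = 5L, field_size_px, seed = 1L) {
  stopifnot(inherits(section, "histology_section"), n_fields >= 1L)
  nr <- nrow(section$tissue_mask); nc <- ncol(section$tissue_mask)
  fs <- as.integer(field_size_px)
  if (fs > nr || fs > nc) stop("field does not fit in section")

  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  off_r <- sample.int(fs, 1L) - 1L
  off_c <- sample.int(fs, 1L) - 1L

  starts_r <- seq.int(1L + off_r, nr - fs + 1L, by = fs)
  starts_c <- seq.int(1L + off_c, nc - fs + 1L, by = fs)
  if (length(starts_r) == 0L || length(starts_c) == 0L) {
    starts_r <- 1L; starts_c <- 1L   # offset pushed the lattice out; anchor it
  }
  cand <- expand.grid(row0 = starts_r, col0 = starts_c)

  usable <- vapply(seq_len(nrow(cand)), function(i) {
    r0 <- cand$row0[i]; c0 <- cand$col0[i]
    !any(section$exclusion_mask[r0:(r0 + fs - 1L), c0:(c0 + fs - 1L)])
  }, logical(1L))
  cand <- cand[usable, , drop = FALSE]
  if (nrow(cand) == 0L) stop("no usable field: exclusion mask covers all candidates")

  if (nrow(cand) < n_fields) {
    warning(sprintf("only %d usable fields available (requested %d)",
                    nrow(cand), n_fields))
    take <- seq_len(nrow(cand))
  } else {
    # spread systematically across the usable candidates
    take <- unique(round(seq(1, nrow(cand), length.out = n_fields)))
    k <- 1L
    while (length(take) < n_fields) {   # rounding collisions: fill greedily
      extra <- setdiff(seq_len(nrow(cand)), take)
      take <- c(take, extra[k]); k <- k + 1L
    }
    take <- sort(take[seq_len(n_fields)])
  }
  out <- cand[take, , drop = FALSE]
  out$size_px <- fs
  out$field_id <- sprintf("F%d", seq_len(nrow(out)))
  rownames(out) <- NULL
  out
}

#' Measure air chords in one field
#'
#' Lays parallel test lines over the field at the given spacing; along each
#' line, contiguous runs of airspace pixels become chords. Runs touching the
#' field border are discarded, as are chords shorter than `min_chord_um`.
#'
#' @param section A [histology_section()].
#' @param field One row of [select_fields()] output (or a list with `row0`,
#'   `col0`, `size_px`); `NULL` measures the whole section as one field.
#' @param orientation `"horizontal"` (lines along rows) or `"vertical"`.
#' @param line_spacing_um Distance between adjacent test lines; at one pixel
#'   spacing every raster line is measured (the exhaustive scan).
#' @param min_chord_um Minimum retained chord length, default 10 um.
#' @return A `chord_set`: list with `orientation`, `lengths_um`, `n_lines`.
#' @export
measure_chords <- function(section, field = NULL,
                           orientation = c("horizontal", "vertical"),
                           line_spacing_um = 50, min_chord_um = 10) {
  stopifnot(inherits(section, "histology_section"))
  orientation <- match.arg(orientation)
  px <- section$pixel_size_um
  if (line_spacing_um < px) stop("line spacing below pixel size")

  mask <- section$tissue_mask
  if (!is.null(field)) {
    r0 <- field$row0; c0 <- field$col0; fs <- field$size_px
    mask <- mask[r0:(r0 + fs - 1L), c0:(c0 + fs - 1L), drop = FALSE]
  }
  if (orientation == "vertical") mask <- t(mask)  # lines along columns

  sp <- max(1L, as.integer(round(line_spacing_um / px)))
  rows <- seq.int(from = min(nrow(mask), max(1L, sp %/% 2L)), to = nrow(mask),
                  by = sp)
  lengths_um <- numeric(0)
  nc <- ncol(mask)
  for (i in rows) {
    runs <- rle(!mask[i, ])
    if (length(runs$lengths) == 0L) next
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    keep <- runs$values & starts > 1L & ends < nc   # air runs, border-free
    if (any(keep)) lengths_um <- c(lengths_um, runs$lengths[keep] * px)
  }
  lengths_um <- lengths_um[lengths_um >= min_chord_um]
  structure(list(orientation = orientation, lengths_um = lengths_um,
                 n_lines = length(rows)),
            class = "chord_set")
}

#' Subject-level mean linear intercept
#'
#' Measures horizontal and vertical chords on systematically selected fields
#' of every section and averages hierarchically without weighting: field mean
#' (pooled orientations) -> section mean of field means -> subject Lm as the
#' mean of section means.
#'
#' @param sections A [histology_section()] or list of them (one subject).
#' @param n_fields Fields per section (default 5).
#' @param field_size_um Field edge length in micrometres (default 600, a
#'   20x-objective capture).
#' @param line_spacing_um Test-line spacing (default 50 um).
#' @param min_chord_um Minimum retained chord (default 10 um).
#' @param seed Seed for field placement.
#' @return An `lm_result`: `lm_um`, `per_section_means_um`, `per_field` data
#'   frame, `n_chords_total`, `undefined` flag (TRUE when no chord survives
#'   anywhere; `lm_um` is then `NA`).
#' @export
compute_lm <- function(sections, n_fields = 5L, field_size_um = 600,
                       line_spacing_um = 50, min_chord_um = 10, seed = 1L) {
  if (inherits(sections, "histology_section")) sections <- list(sections)
  stopifnot(length(sections) >= 1L)

  per_field <- list()
  sec_means <- numeric(0)
  n_total <- 0L
  for (s in seq_along(sections)) {
    sec <- sections[[s]]
    fs_px <- max(2L, as.integer(round(field_size_um / sec$pixel_size_um)))
    flds <- select_fields(sec, n_fields = n_fields, field_size_px = fs_px,
                          seed = seed + s)
    fmeans <- numeric(0)
    for (i in seq_len(nrow(flds))) {
      fld <- flds[i, ]
      ch <- c(measure_chords(sec, fld, "horizontal", line_spacing_um,
                             min_chord_um)$lengths_um,
              measure_chords(sec, fld, "vertical", line_spacing_um,
                             min_chord_um)$lengths_um)
      n_total <- n_total + length(ch)
      fmean <- if (length(ch)) mean(ch) else NA_real_
      fmeans <- c(fmeans, fmean)
      per_field[[length(per_field) + 1L]] <- data.frame(
        subject_id = sec$subject_id, section_id = sec$section_id,
        field_id = fld$field_id, n_chords = length(ch),
        mean_chord_um = fmean)
    }
    sec_means <- c(sec_means, mean(fmeans, na.rm = TRUE))
  }
  sec_means[is.nan(sec_means)] <- NA_real_
  lm_um <- mean(sec_means, na.rm = TRUE)
  undefined <- n_total == 0L
  if (undefined) lm_um <- NA_real_
  structure(list(lm_um = lm_um,
                 per_section_means_um = sec_means,
                 per_field = do.call(rbind, per_field),
                 n_chords_total = n_total,
                 undefined = undefined,
                 params = list(n_fields = n_fields,
                               field_size_um = field_size_um,
                               line_spacing_um = line_spacing_um,
                               min_chord_um = min_chord_um)),
            class = "lm_result")
}

#' @export
print.lm_result <- function(x, ...) {
  if (x$undefined) {
    cat("Lm undefined: no chords survived the minimum-length filter\n")
  } else {
    cat(sprintf("Lm = %.2f um (%d sections, %d chords)\n", x$lm_um,
                length(x$per_section_means_um), x$n_chords_total))
  }
  invisible(x)
}

#' Exhaustive mean chord length of a whole mask
#'
#' Measures every raster line (1 px spacing), both orientations, over the full
#' section; the mean of all surviving chords. Used as the ground-truth airspace
#' chord length of generated phantoms, where it serves as the reference the
#' field-sampled estimator is validated against.
#'
#' @inheritParams measure_chords
#' @return Mean chord length in micrometres (`NA` when no chord survives).
#' @export
exhaustive_mean_chord <- function(section, min_chord_um = 10) {
  ch <- c(measure_chords(section, NULL, "horizontal",
                         line_spacing_um = section$pixel_size_um,
                         min_chord_um = min_chord_um)$lengths_um,
          measure_chords(section, NULL, "vertical",
                         line_spacing_um = section$pixel_size_um,
                         min_chord_um = min_chord_um)$lengths_um)
  if (length(ch) == 0L) return(NA_real_)
  mean(ch)
}

# RNG bookkeeping: seeded functions must not disturb the caller's stream
.save_rng <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv())
  else NULL
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}
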