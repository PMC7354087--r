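# Whole-cohort synthesis.
#
# The default design mirrors a 12-week cigarette-smoke exposure study in
# female BALB/c mice: three groups (fresh-air control, CS, CS with
# interventional nebulised azithromycin from week 7), n = 5 per group,
# histology and leukocyte scoring post mortem at week 12 (3 sections/subject,
# 5 fields/section), micro-CT and T2-weighted MRI at weeks 0, 6, 8, 10, 12.
#
# Group effect parameters reproduce the magnitudes that characterise such a
# study: a ~22% Lm increase under CS (recovered under azithromycin), lung
# density falling to about -400 HU under CS against about -385 HU in controls,
# a ~27% higher lung/muscle T2 ratio under CS, and infiltration-focus
# densities near 1, 11 and 5 per 20 mm^2 for control, CS and CS+Azi. A
# per-subject latent severity couples all four modalities, giving the
# cross-modality correlations their sign.

#' Study design
#'
#' @param groups Named list of group specifications; each a list with
#'   `n_subjects` and effect parameters: `emphysema_fraction`, `period_mult`
#'   (histology), `hu_by_week` (named numeric, anchors interpolated over
#'   `timepoints`), `t2_ratio`, `t2_kidney_ratio`, `foci_per_20mm2`.
#' @param timepoints Imaging weeks.
#' @param sections_per_subject Histology sections per subject.
#' @param fields_per_subject Stereology fields per section.
#' @param histology_size_px,histology_pixel_um Mask geometry.
#' @param field_size_um Stereology field edge, um.
#' @param foci_section_um Edge length of the square whole-section frame over
#'   which leukocytes are scored, um.
#' @param ct_shape,ct_noise_sd_hu CT volume shape and HU noise.
#' @param mr_shape,mr_noise_sd MR slice shape and intensity noise.
#' @param severity_sd Per-subject latent severity SD (dimensionless).
#' @return A `study_design` list.
#' @export
study_design <- function(groups = NULL,
                         timepoints = c(0, 6, 8, 10, 12),
                         sections_per_subject = 3L,
                         fields_per_subject = 5L,
                         histology_size_px = 900L,
                         histology_pixel_um = 2,
                         field_size_um = 400,
                         foci_section_um = 6000,
                         ct_shape = c(24L, 24L, 24L),
                         ct_noise_sd_hu = 5,
                         mr_shape = c(48L, 48L),
                         mr_noise_sd = 3,
                         severity_sd = 1) {
  if (is.null(groups)) {
    groups <- list(
      control = list(n_subjects = 5L, emphysema_fraction = 0,
                     period_mult = 1,
                     hu_by_week = c("0" = -357, "6" = -373.9, "12" = -384.9),
                     t2_ratio = 1.10, t2_kidney_ratio = 1.20,
                     foci_per_20mm2 = 1.1),
      CS = list(n_subjects = 5L, emphysema_fraction = 0.19,
                period_mult = 1,
                hu_by_week = c("0" = -357, "6" = -399.1, "12" = -399.5),
                t2_ratio = 1.40, t2_kidney_ratio = 1.55,
                foci_per_20mm2 = 10.98),
      CS_Azi = list(n_subjects = 5L, emphysema_fraction = 0,
                    period_mult = 0.96,
                    hu_by_week = c("0" = -357, "6" = -399.1, "12" = -377.3),
                    t2_ratio = 1.13, t2_kidney_ratio = 1.25,
                    foci_per_20mm2 = 5.147))
  }
  for (g in groups) if (is.null(g$n_subjects) || g$n_subjects < 1L)
    stop("every group needs n_subjects >= 1")
  structure(list(groups = groups, timepoints = timepoints,
                 sections_per_subject = as.integer(sections_per_subject),
                 fields_per_subject = as.integer(fields_per_subject),
                 histology_size_px = as.integer(histology_size_px),
                 histology_pixel_um = histology_pixel_um,
                 field_size_um = field_size_um,
                 foci_section_um = foci_section_um,
                 ct_shape = as.integer(ct_shape),
                 ct_noise_sd_hu = ct_noise_sd_hu,
                 mr_shape = as.integer(mr_shape),
                 mr_noise_sd = mr_noise_sd,
                 severity_sd = severity_sd,
                 period_um = 48, septum_um = 7),
            class = "study_design")
}

# deterministic sub-seed, kept well below 2^31
.sub_seed <- function(seed, i, k) {
  ((as.integer(seed) %% 100000L) * 10000L + i * 97L + k) %% 2147483647L
}

.interp_week <- function(hu_by_week, week) {
  w <- as.numeric(names(hu_by_week))
  stats::approx(w, hu_by_week, xout = week, rule = 2)$y
}

#' Generate a synthetic study to disk
#'
#' Writes one directory per subject containing histology mask TIFFs and
#' leukocyte CSVs (terminal week) and CT/MR NIfTI pairs (every timepoint),
#' plus `manifest.csv` mapping subject, group, week and modality to files and
#' their ground truth. Re-running with the same design and seed reproduces the
#' tree byte for byte.
#'
#' @param design A [study_design()].
#' @param dir Output directory (created; must be writable).
#' @param seed Master integer seed.
#' @return The manifest data frame (invisibly carries `manifest_dir`).
#' @export
generate_study <- function(design, dir, seed = 1L) {
  stopifnot(inherits(design, "study_design"))
  ok <- dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir)) stop("unwritable output path: ", dir)

  rows <- list()
  add_row <- function(subject, group, week, modality, path, px = NA, area = NA,
                      aux = NA, truth = list()) {
    rows[[length(rows) + 1L]] <<- data.frame(
      subject_id = subject, group = group, week = week, modality = modality,
      path = path, pixel_size_um = px, area_mm2 = area, aux_path = aux,
      truth_json = as.character(jsonlite::toJSON(truth, auto_unbox = TRUE,
                                                 digits = 10)))
  }

  week_max <- max(design$timepoints)
  subj_i <- 0L
  for (gname in names(design$groups)) {
    g <- design$groups[[gname]]
    for (j in seq_len(g$n_subjects)) {
      subj_i <- subj_i + 1L
      sid <- sprintf("%s_%02d", gname, j)
      sdir <- file.path(dir, sid)
      dir.create(sdir, showWarnings = FALSE)

      old <- .save_rng()
      set.seed(.sub_seed(seed, subj_i, 0L))
      z <- stats::rnorm(1L, 0, design$severity_sd)
      .restore_rng(old)

      ef <- min(1, max(0, g$emphysema_fraction + 0.015 * z))
      period <- design$period_um * g$period_mult * (1 + 0.02 * z)
      t2 <- g$t2_ratio * (1 + 0.03 * z)
      t2k <- g$t2_kidney_ratio * (1 + 0.03 * z)
      foci_dens <- max(0, g$foci_per_20mm2 * (1 + 0.25 * z))

      # histology + leukocytes: terminal week
      for (s in seq_len(design$sections_per_subject)) {
        gen <- generate_alveolar_section(
          "voronoi_foam", period_um = period, septum_um = design$septum_um,
          emphysema_fraction = ef, size_px = design$histology_size_px,
          pixel_size_um = design$histology_pixel_um,
          seed = .sub_seed(seed, subj_i, s))
        hp <- file.path(sid, sprintf("histo_S%d.tif", s))
        write_histology_tiff(gen$section, file.path(dir, hp))
        add_row(sid, gname, week_max, "histology", hp,
                px = design$histology_pixel_um,
                truth = c(gen$truth, list(severity = z)))

        # leukocytes are scored over the whole section, a larger frame than
        # the stereology mask crop
        area_mm2 <- (design$foci_section_um / 1000)^2
        n_foci <- round(foci_dens * area_mm2 / 20)
        inj <- inject_leukocyte_foci(
          list(width_um = design$foci_section_um,
               height_um = design$foci_section_um,
               section_id = sprintf("S%d", s), subject_id = sid),
          n_foci = n_foci, seed = .sub_seed(seed, subj_i, 10L + s))
        fp <- file.path(sid, sprintf("cells_S%d.csv", s))
        write_points_csv(inj$points, file.path(dir, fp))
        add_row(sid, gname, week_max, "foci", fp, area = area_mm2,
                truth = list(true_n_foci = inj$truth$true_n_foci,
                             true_foci_per_20mm2 = foci_density(n_foci, area_mm2)))
      }

      # CT and MR at every timepoint
      for (w in design$timepoints) {
        hu <- .interp_week(g$hu_by_week, w) - 4 * z
        ct <- generate_ct_volume(hu, design$ct_noise_sd_hu, design$ct_shape,
                                 seed = .sub_seed(seed, subj_i, 100L + w))
        labs <- ct$labels
        labs[ct$voi] <- 6L
        cp <- file.path(sid, sprintf("ct_w%02d.nii", w))
        lp <- file.path(sid, sprintf("ct_w%02d_labels.nii", w))
        write_volume_nifti(ct$raw, file.path(dir, cp))
        write_volume_nifti(labs, file.path(dir, lp))
        add_row(sid, gname, w, "ct", cp, aux = lp,
                truth = list(true_lung_hu = hu, gain = ct$truth$gain,
                             offset = ct$truth$offset))

        muscle <- 250
        mr <- generate_mr_slice(muscle * t2, muscle, muscle * t2k,
                                design$mr_noise_sd, design$mr_shape,
                                seed = .sub_seed(seed, subj_i, 200L + w))
        mp <- file.path(sid, sprintf("mr_w%02d.nii", w))
        mlp <- file.path(sid, sprintf("mr_w%02d_labels.nii", w))
        write_volume_nifti(mr$image, file.path(dir, mp))
        write_volume_nifti(mr$labels, file.path(dir, mlp))
        add_row(sid, gname, w, "mri", mp, aux = mlp,
                truth = list(true_t2_ratio = t2, true_kidney_ratio = t2k))
      }
    }
  }
  mf <- do.call(rbind, rows)
  utils::write.csv(mf, file.path(dir, "manifest.csv"), row.names = FALSE)
  attr(mf, "manifest_dir") <- normalizePath(dir)
  invisible(mf)
}
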