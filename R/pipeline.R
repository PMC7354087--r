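# Orchestration: simulate -> quantify (lm, foci, ct, mri) -> stats -> report.
#
# Every stage reads and writes the shared CSV dialect, so the statistics stage
# can be re-run on frozen quantification tables and reproduce its section of
# the report unchanged.

#' Build a pipeline run configuration
#'
#' All parameters are explicit after defaulting; the effective configuration
#' is embedded in the report, so no default is silent. Configurations
#' round-trip losslessly through [write_run_config()] / [read_run_config()].
#'
#' @param out_dir Output directory for the dataset and result tables.
#' @param seed Master seed for simulation and field placement.
#' @param design A [study_design()] (used by the simulate stage).
#' @param stages Character vector of stages to run, in order, from
#'   `c("simulate", "lm", "foci", "ct", "mri", "stats")`.
#' @param manifest Path to an existing manifest (required when `"simulate"`
#'   is not among the stages); `NULL` means `<out_dir>/data/manifest.csv`.
#' @param n_fields,field_size_um,line_spacing_um,min_chord_um Stereology
#'   parameters (fields per section; um).
#' @param linking_radius_um,min_cells Focus detection parameters.
#' @param lung_window CT lung threshold window, HU; `NULL` disables
#'   windowing and averages the full VOI.
#' @param baseline_week Reference week for percentage changes.
#' @param analysis_week Week at which group comparisons and cross-modality
#'   correlations are evaluated.
#' @param comparisons List of 2-vectors of group names to test pairwise;
#'   `NULL` means all pairs.
#' @return A `run_config` list.
#' @export
run_config <- function(out_dir, seed = 1L, design = study_design(),
                       stages = c("simulate", "lm", "foci", "ct", "mri",
                                  "stats"),
                       manifest = NULL,
                       n_fields = NULL, field_size_um = NULL,
                       line_spacing_um = 50, min_chord_um = 10,
                       linking_radius_um = 25, min_cells = 21L,
                       lung_window = c(-900, -100),
                       baseline_week = 0, analysis_week = NULL,
                       comparisons = NULL) {
  stages <- match.arg(stages, several.ok = TRUE)
  if (is.null(n_fields)) n_fields <- design$fields_per_subject
  if (is.null(field_size_um)) field_size_um <- design$field_size_um
  if (is.null(analysis_week)) analysis_week <- max(design$timepoints)
  structure(list(out_dir = out_dir, seed = as.integer(seed), design = design,
                 stages = stages, manifest = manifest,
                 n_fields = n_fields, field_size_um = field_size_um,
                 line_spacing_um = line_spacing_um,
                 min_chord_um = min_chord_um,
                 linking_radius_um = linking_radius_um,
                 min_cells = min_cells, lung_window = lung_window,
                 baseline_week = baseline_week,
                 analysis_week = analysis_week,
                 comparisons = comparisons),
            class = "run_config")
}

#' Write / read a run configuration as YAML
#'
#' @param config A [run_config()].
#' @param path YAML file path.
#' @return `path` invisibly; [read_run_config()] returns the `run_config`.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  x <- unclass(config)
  x$design <- unclass(x$design)
  x$design$groups <- lapply(x$design$groups,
                            function(g) { g$hu_by_week <- as.list(g$hu_by_week); g })
  yaml::write_yaml(x, path, precision = 15L)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  x$design$groups <- lapply(x$design$groups, function(g) {
    g$hu_by_week <- unlist(g$hu_by_week)
    g
  })
  d <- x$design
  design <- study_design(groups = d$groups, timepoints = d$timepoints,
                         sections_per_subject = d$sections_per_subject,
                         fields_per_subject = d$fields_per_subject,
                         histology_size_px = d$histology_size_px,
                         histology_pixel_um = d$histology_pixel_um,
                         field_size_um = d$field_size_um,
                         foci_section_um = d$foci_section_um,
                         ct_shape = d$ct_shape,
                         ct_noise_sd_hu = d$ct_noise_sd_hu,
                         mr_shape = d$mr_shape, mr_noise_sd = d$mr_noise_sd,
                         severity_sd = d$severity_sd)
  run_config(out_dir = x$out_dir, seed = x$seed, design = design,
             stages = x$stages, manifest = x$manifest,
             n_fields = x$n_fields, field_size_um = x$field_size_um,
             line_spacing_um = x$line_spacing_um,
             min_chord_um = x$min_chord_um,
             linking_radius_um = x$linking_radius_um,
             min_cells = x$min_cells,
             lung_window = if (length(x$lung_window)) unlist(x$lung_window),
             baseline_week = x$baseline_week,
             analysis_week = x$analysis_week,
             comparisons = x$comparisons)
}

#' Quantify mean linear intercept for every subject in a manifest
#'
#' @param manifest A [read_manifest()] data frame (or [generate_study()]
#'   output).
#' @param n_fields,field_size_um,line_spacing_um,min_chord_um Stereology
#'   parameters.
#' @param seed Field-placement seed.
#' @return Data frame: one row per subject with `lm_um` plus per-section
#'   means, and a `per_field` attribute with the field-level table.
#' @export
quantify_lm <- function(manifest, n_fields = 5L, field_size_um = 400,
                        line_spacing_um = 50, min_chord_um = 10, seed = 1L) {
  mh <- manifest[manifest$modality == "histology", , drop = FALSE]
  if (nrow(mh) == 0L) stop("manifest has no histology rows")
  out <- list(); fields <- list()
  for (sid in unique(mh$subject_id)) {
    rows <- mh[mh$subject_id == sid, , drop = FALSE]
    secs <- lapply(seq_len(nrow(rows)), function(i)
      read_histology_tiff(.resolve_path(manifest, rows$path[i]),
                          pixel_size_um = rows$pixel_size_um[i],
                          section_id = sprintf("S%d", i), subject_id = sid))
    res <- compute_lm(secs, n_fields = n_fields,
                      field_size_um = field_size_um,
                      line_spacing_um = line_spacing_um,
                      min_chord_um = min_chord_um, seed = seed)
    out[[sid]] <- data.frame(subject_id = sid, group = rows$group[1L],
                             lm_um = res$lm_um,
                             n_chords = res$n_chords_total)
    fields[[sid]] <- res$per_field
  }
  df <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  attr(df, "per_field") <- do.call(rbind, c(fields,
                                            list(make.row.names = FALSE)))
  df
}

#' Quantify leukocyte focus density for every subject
#'
#' @param manifest Manifest data frame.
#' @param linking_radius_um,min_cells Detection parameters.
#' @return Data frame per subject: `foci_per_20mm2` (mean over sections),
#'   `n_foci_total`; attribute `per_section` with the section table.
#' @export
quantify_foci <- function(manifest, linking_radius_um = 25, min_cells = 21L) {
  mf <- manifest[manifest$modality == "foci", , drop = FALSE]
  if (nrow(mf) == 0L) stop("manifest has no leukocyte rows")
  per_sec <- list(); out <- list()
  for (sid in unique(mf$subject_id)) {
    rows <- mf[mf$subject_id == sid, , drop = FALSE]
    dens <- numeric(0); ntot <- 0L
    for (i in seq_len(nrow(rows))) {
      pts <- read_points_csv(.resolve_path(manifest, rows$path[i]),
                             section_area_mm2 = rows$area_mm2[i],
                             section_id = sprintf("S%d", i), subject_id = sid)
      det <- detect_foci(pts, linking_radius_um, min_cells)
      dens <- c(dens, det$foci_per_20mm2); ntot <- ntot + det$n_foci
      per_sec[[length(per_sec) + 1L]] <- data.frame(
        subject_id = sid, section_id = sprintf("S%d", i),
        n_foci = det$n_foci, area_mm2 = rows$area_mm2[i],
        foci_per_20mm2 = det$foci_per_20mm2)
    }
    out[[sid]] <- data.frame(subject_id = sid, group = rows$group[1L],
                             foci_per_20mm2 = mean(dens),
                             n_foci_total = ntot)
  }
  df <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  attr(df, "per_section") <- do.call(rbind, c(per_sec,
                                              list(make.row.names = FALSE)))
  df
}

#' Quantify mean lung HU for every subject and week
#'
#' Calibration anchors (water and air raw means) are measured from the label
#' volume accompanying each scan; the VOI is label code 6.
#'
#' @param manifest Manifest data frame.
#' @param lung_window HU window restricting the averaged voxels; `NULL`
#'   averages the full VOI.
#' @return Data frame: `subject_id`, `group`, `week`, `mean_hu`,
#'   `n_voxels_used`.
#' @export
quantify_ct <- function(manifest, lung_window = c(-900, -100)) {
  mc <- manifest[manifest$modality == "ct", , drop = FALSE]
  if (nrow(mc) == 0L) stop("manifest has no CT rows")
  out <- lapply(seq_len(nrow(mc)), function(i) {
    raw <- read_volume_nifti(.resolve_path(manifest, mc$path[i]))
    labs <- read_labels_nifti(.resolve_path(manifest, mc$aux_path[i]))
    cal <- calibrate_hu(raw, water_raw_mean = mean(raw[labs == 4L]),
                        air_raw_mean = mean(raw[labs == 5L]))
    voi <- labs == 6L
    lung_mask <- if (is.null(lung_window)) NULL else
      segment_lung(cal, lung_window)
    res <- mean_hu(cal, voi, lung_mask)
    data.frame(subject_id = mc$subject_id[i], group = mc$group[i],
               week = mc$week[i], mean_hu = res$mean_hu,
               n_voxels_used = res$n_voxels_used)
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Quantify T2 intensity ratios for every subject and week
#'
#' @param manifest Manifest data frame.
#' @return Data frame: `subject_id`, `group`, `week`, `t2_ratio_lung`,
#'   `t2_ratio_kidney`.
#' @export
quantify_mri <- function(manifest) {
  mm <- manifest[manifest$modality == "mri", , drop = FALSE]
  if (nrow(mm) == 0L) stop("manifest has no MRI rows")
  out <- lapply(seq_len(nrow(mm)), function(i) {
    img <- read_volume_nifti(.resolve_path(manifest, mm$path[i]))
    labs <- read_labels_nifti(.resolve_path(manifest, mm$aux_path[i]))
    res <- t2_ratio(list(image = img, labels = labs))
    data.frame(subject_id = mm$subject_id[i], group = mm$group[i],
               week = mm$week[i], t2_ratio_lung = res$ratio_lung,
               t2_ratio_kidney = res$ratio_kidney)
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Run the full pipeline
#'
#' Executes the enabled stages in order (simulate, lm, foci, ct, mri, stats),
#' writing `lm.csv`, `foci.csv`, `ct.csv`, `mri.csv`, `measurements.csv` and
#' `report.json` under the output directory. Stages not enabled read their
#' inputs from the existing CSVs, so the statistics stage can be re-run on
#' frozen quantification tables.
#'
#' @param config A [run_config()].
#' @return A `study_report`: `measurements` (wide per-subject table at the
#'   analysis week), `tests`, `correlations`, `summaries`, `recovery`
#'   (measured vs ground truth), `config`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  data_dir <- file.path(config$out_dir, "data")
  stage <- function(s) s %in% config$stages
  csv <- function(name) file.path(config$out_dir, name)

  manifest_path <- if (!is.null(config$manifest)) config$manifest else
    file.path(data_dir, "manifest.csv")
  if (stage("simulate")) {
    message("stage simulate: writing ", data_dir,
            " (seed ", config$seed, ")")
    generate_study(config$design, data_dir, seed = config$seed)
  }
  manifest <- read_manifest(manifest_path)

  lm_df <- if (stage("lm")) {
    message("stage lm: fields=", config$n_fields,
            " field_size_um=", config$field_size_um,
            " line_spacing_um=", config$line_spacing_um,
            " min_chord_um=", config$min_chord_um)
    df <- quantify_lm(manifest, config$n_fields, config$field_size_um,
                      config$line_spacing_um, config$min_chord_um,
                      seed = config$seed)
    utils::write.csv(df, csv("lm.csv"), row.names = FALSE); df
  } else if (file.exists(csv("lm.csv"))) utils::read.csv(csv("lm.csv"))

  foci_df <- if (stage("foci")) {
    message("stage foci: radius_um=", config$linking_radius_um,
            " min_cells=", config$min_cells)
    df <- quantify_foci(manifest, config$linking_radius_um, config$min_cells)
    utils::write.csv(df, csv("foci.csv"), row.names = FALSE); df
  } else if (file.exists(csv("foci.csv"))) utils::read.csv(csv("foci.csv"))

  ct_df <- if (stage("ct")) {
    message("stage ct: lung_window=",
            if (is.null(config$lung_window)) "none" else
              paste(config$lung_window, collapse = ":"))
    df <- quantify_ct(manifest, config$lung_window)
    utils::write.csv(df, csv("ct.csv"), row.names = FALSE); df
  } else if (file.exists(csv("ct.csv"))) utils::read.csv(csv("ct.csv"))

  mri_df <- if (stage("mri")) {
    message("stage mri")
    df <- quantify_mri(manifest)
    utils::write.csv(df, csv("mri.csv"), row.names = FALSE); df
  } else if (file.exists(csv("mri.csv"))) utils::read.csv(csv("mri.csv"))

  report <- NULL
  if (stage("stats")) {
    message("stage stats: analysis_week=", config$analysis_week)
    report <- .stats_stage(config, manifest, lm_df, foci_df, ct_df, mri_df)
    utils::write.csv(report$measurements, csv("measurements.csv"),
                     row.names = FALSE)
    jsonlite::write_json(.report_json(report), csv("report.json"),
                         auto_unbox = TRUE, digits = 10, pretty = TRUE)
  }
  invisible(report)
}

.stats_stage <- function(config, manifest, lm_df, foci_df, ct_df, mri_df) {
  wk <- config$analysis_week
  meas <- NULL
  merge_in <- function(meas, df) {
    if (is.null(df)) return(meas)
    if (is.null(meas)) df else merge(meas, df, all = TRUE,
                                     by = c("subject_id", "group"))
  }
  ct_wk <- if (!is.null(ct_df))
    ct_df[ct_df$week == wk, c("subject_id", "group", "mean_hu")]
  mri_wk <- if (!is.null(mri_df))
    mri_df[mri_df$week == wk, c("subject_id", "group", "t2_ratio_lung",
                                "t2_ratio_kidney")]
  meas <- merge_in(meas, lm_df[, c("subject_id", "group", "lm_um")])
  meas <- merge_in(meas, foci_df[, c("subject_id", "group", "foci_per_20mm2")])
  meas <- merge_in(meas, ct_wk)
  meas <- merge_in(meas, mri_wk)
  meas <- meas[order(meas$subject_id), , drop = FALSE]

  groups <- unique(meas$group)
  comparisons <- config$comparisons
  if (is.null(comparisons) && length(groups) >= 2L)
    comparisons <- utils::combn(sort(groups), 2L, simplify = FALSE)

  modalities <- intersect(c("lm_um", "foci_per_20mm2", "mean_hu",
                            "t2_ratio_lung", "t2_ratio_kidney"), names(meas))
  tests <- list(); summaries <- list()
  for (m in modalities) {
    for (g in sort(groups)) {
      v <- meas[[m]][meas$group == g]
      v <- v[!is.na(v)]
      if (length(v))
        summaries[[paste(m, g, sep = "|")]] <-
          c(list(modality = m, group = g), summarize_group(v))
    }
    for (cmp in comparisons) {
      a <- meas[[m]][meas$group == cmp[1L]]
      b <- meas[[m]][meas$group == cmp[2L]]
      a <- a[!is.na(a)]; b <- b[!is.na(b)]
      if (length(a) && length(b)) {
        tst <- mann_whitney_exact(a, b)
        med <- fold_change(stats::median(a), stats::median(b))
        tests[[paste(m, cmp[1L], cmp[2L], sep = "|")]] <-
          list(modality = m, group_a = cmp[1L], group_b = cmp[2L],
               U = tst$statistic, p_two_sided = tst$p_two_sided,
               exact = tst$exact, fold_change = med$fold)
      }
    }
    # Kruskal-Wallis across all groups at the analysis week
    gl <- lapply(sort(groups), function(g) {
      v <- meas[[m]][meas$group == g]; v[!is.na(v)]
    })
    gl <- gl[lengths(gl) > 0L]
    if (length(gl) >= 2L) {
      kw <- kruskal_wallis(gl)
      tests[[paste(m, "kruskal_wallis", sep = "|")]] <-
        list(modality = m, H = kw$statistic, p_two_sided = kw$p_two_sided,
             exact = kw$exact)
    }
  }

  # longitudinal CT: Kruskal-Wallis on percentage change from baseline
  if (!is.null(ct_df)) {
    for (w in setdiff(sort(unique(ct_df$week)), config$baseline_week)) {
      pc <- lapply(sort(groups), function(g) {
        sub <- ct_df[ct_df$group == g, ]
        vapply(unique(sub$subject_id), function(sid) {
          s <- sub[sub$subject_id == sid, ]
          p <- percent_change(s$mean_hu, s$week, config$baseline_week)
          if (is.null(p) || !as.character(w) %in% names(p)) NA_real_
          else p[[as.character(w)]]
        }, numeric(1L))
      })
      pc <- lapply(pc, function(v) v[!is.na(v)])
      pc <- pc[lengths(pc) > 0L]
      if (length(pc) >= 2L) {
        kw <- kruskal_wallis(pc)
        tests[[paste0("ct_pct_change_w", w, "|kruskal_wallis")]] <-
          list(modality = "ct_pct_change", week = w, H = kw$statistic,
               p_two_sided = kw$p_two_sided, exact = kw$exact)
      }
    }
  }

  correlations <- correlate_modalities(meas)
  recovery <- .recovery_table(manifest, meas, wk)
  structure(list(measurements = meas, tests = tests,
                 correlations = correlations, summaries = summaries,
                 recovery = recovery, config = config),
            class = "study_report")
}

#' Cross-modality Spearman correlations
#'
#' Correlates subject-level measurements across modality pairs at the analysis
#' week (HU vs Lm, T2 vs HU, T2 vs Lm, T2 vs foci by default), over subjects
#' with both values present.
#'
#' @param measurements Wide per-subject data frame (a `study_report`'s
#'   `measurements` element, or the report itself).
#' @param pairs List of 2-vectors of column names to correlate.
#' @return Data frame: `var_a`, `var_b`, `rho`, `p_two_sided`, `n`, `exact`;
#'   pairs with fewer than 3 complete subjects are skipped with a warning.
#' @export
correlate_modalities <- function(measurements,
                                 pairs = list(c("mean_hu", "lm_um"),
                                              c("t2_ratio_lung", "mean_hu"),
                                              c("t2_ratio_lung", "lm_um"),
                                              c("t2_ratio_lung",
                                                "foci_per_20mm2"))) {
  if (inherits(measurements, "study_report"))
    measurements <- measurements$measurements
  out <- list()
  for (pr in pairs) {
    if (!all(pr %in% names(measurements))) next
    ok <- stats::complete.cases(measurements[, pr])
    if (sum(ok) < 3L) {
      warning("fewer than 3 shared subjects for ", pr[1L], " vs ", pr[2L],
              ": skipped")
      next
    }
    sp <- spearman(measurements[[pr[1L]]][ok], measurements[[pr[2L]]][ok])
    out[[length(out) + 1L]] <- data.frame(
      var_a = pr[1L], var_b = pr[2L], rho = sp$rho,
      p_two_sided = sp$p_two_sided, n = sp$n, exact = sp$exact)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

.recovery_table <- function(manifest, meas, wk) {
  truth_of <- function(modality, field) {
    rows <- manifest[manifest$modality == modality &
                       manifest$week == wk, , drop = FALSE]
    if (nrow(rows) == 0L) return(NULL)
    vals <- vapply(seq_len(nrow(rows)), function(i) {
      tr <- jsonlite::fromJSON(rows$truth_json[i])
      if (is.null(tr[[field]])) NA_real_ else as.numeric(tr[[field]])
    }, numeric(1L))
    tapply(vals, rows$subject_id, mean)
  }
  truths <- list(lm_um = truth_of("histology", "true_mean_chord_um"),
                 foci_per_20mm2 = truth_of("foci", "true_foci_per_20mm2"),
                 mean_hu = truth_of("ct", "true_lung_hu"),
                 t2_ratio_lung = truth_of("mri", "true_t2_ratio"))
  out <- list()
  for (m in names(truths)) {
    tr <- truths[[m]]
    if (is.null(tr) || !m %in% names(meas)) next
    idx <- match(meas$subject_id, names(tr))
    out[[m]] <- data.frame(subject_id = meas$subject_id,
                           modality = m, true_value = as.numeric(tr[idx]),
                           measured_value = meas[[m]])
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

.report_json <- function(report) {
  cfg <- unclass(report$config)
  cfg$design <- unclass(cfg$design)
  list(config = cfg,
       measurements = report$measurements,
       summaries = unname(report$summaries),
       tests = unname(report$tests),
       correlations = report$correlations,
       recovery = report$recovery)
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("study_report: %d subjects, %d tests, %d correlations\n",
              nrow(x$measurements), length(x$tests),
              NROW(x$correlations)))
  invisible(x)
}
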