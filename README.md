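# emphyquant

Quantitative readouts of emphysema-like change in mouse models of
cigarette-smoke-induced COPD, implemented as explicit, testable procedures
with a synthetic ground-truth generator and exact small-sample statistics.

Smoke-exposure studies read out alveolar destruction and inflammation
through four measurements that this package implements end to end:

* **Mean linear intercept (Lm)** — grid-overlay stereology on binary tissue
  masks: parallel test lines are laid over systematically sampled fields,
  maximal airspace runs along each line become chords (border-clipped runs
  discarded, minimum length 10 µm), and
  `Lm = mean(chords) → mean(fields) → mean(sections)`, unweighted at every
  level. Larger Lm means larger airspaces, i.e. emphysema-like change.
* **Leukocyte infiltration foci** — single-linkage spatial clustering of
  cell coordinates (default linking radius 25 µm); clusters of **more than
  20** cells are foci, expressed as `n × 20 / area_mm²` per 20 mm² of
  section.
* **Micro-CT lung densitometry** — two-point Hounsfield calibration
  `HU(v) = 1000·(v − water)/(water − air)` (water → 0, air → −1000, clamped
  to ±1000), then mean HU over a supplied lung VOI, optionally restricted
  to a [−900, −100] HU lung window.
* **T2-weighted MRI ratios** — mean lung (and kidney) intensity divided by
  arm-muscle intensity in the same slice; scanner gain cancels exactly.

Group comparisons use exact enumeration: the two-sided Mann–Whitney p at
small n is `min(1, 2·tail)` over all `C(n1+n2, n1)` rank assignments (so
complete separation at 5 v 5 gives 2/252 = .0079), with exact
Wilcoxon signed-rank, tie-corrected Kruskal–Wallis, and Spearman
correlation (exact permutation p for n ≤ 9) alongside.

Because no public dataset accompanies studies of this kind, the package
includes first-class generators: Voronoi-foam alveolar masks whose true
mean chord is established by exhaustive 1-px scanning (emphysema modelled
as seeded removal of a fraction of shared septal walls), connected-by-
construction leukocyte clusters, affine-distorted raw CT phantoms with
water/air anchors, and labelled MR slices — plus `generate_study()`, which
writes a complete multi-modality cohort (TIFF/CSV/NIfTI + manifest) with a
per-subject latent severity coupling all modalities.

## Worked example

```r
library(emphyquant)

# analytic phantom: period 50 um, septum 10 um => every air chord is 40 um
ph <- generate_alveolar_section("parallel_septa", period_um = 50,
                                septum_um = 10, size_px = 400,
                                pixel_size_um = 1, seed = 1)
compute_lm(ph$section, n_fields = 4, field_size_um = 150, seed = 1)
#> Lm = 40.00 um (1 sections, 36 chords)

# foam phantom with 19% of septal walls removed; truth by exhaustive scan
fm <- generate_alveolar_section("voronoi_foam", emphysema_fraction = 0.19,
                                size_px = 1800, pixel_size_um = 2, seed = 7)
round(fm$truth$true_mean_chord_um, 2)
#> [1] 40.6
compute_lm(fm$section, n_fields = 15, field_size_um = 700, seed = 11)
#> Lm = 40.35 um (1 sections, 4816 chords)

# exact two-group test on subject Lm values (one inverted pair, U = 1)
mann_whitney_exact(c(38.95, 40.8, 42.45, 44.0, 53.1),
                   c(29.0, 34.7, 36.2, 40.22))
#> mann_whitney test (exact enumeration)
#>   statistic = 19, two-sided p = 0.03175
#>   n = 5 vs 4

# leukocyte foci: 4 injected clusters on a 36 mm^2 section frame
inj <- inject_leukocyte_foci(list(width_um = 6000, height_um = 6000),
                             n_foci = 4, seed = 2)
detect_foci(inj$points)
#> 4 foci among 180 cells over 36.00 mm^2: 2.222 foci / 20 mm^2

# CT phantom: calibrate from the water/air regions, average the lung VOI
ct  <- generate_ct_volume(lung_mean_hu = -399.5, noise_sd_hu = 20, seed = 3)
cal <- calibrate_hu(ct$raw, mean(ct$raw[ct$labels == 4]),
                    mean(ct$raw[ct$labels == 5]))
mean_hu(cal, ct$voi, segment_lung(cal))
#> mean lung density -399.4 HU over 1824 voxels (range -462.5 to -330.2)
```

The Lm prints say the estimator recovered the analytic 40 µm exactly and
the foam's exhaustively measured 40.6 µm to within 1%; the Mann–Whitney
print is the exact enumerated p for a 5-vs-4 design with a single inverted
pair; the CT print shows the −399.5 HU phantom recovered to 0.1 HU through
an unknown affine raw scale.

A full cohort run is one call:

```r
cfg <- run_config(out_dir = "run1", seed = 1)   # default 3-group design
rep <- run_pipeline(cfg)                        # simulate -> quantify -> stats
rep$measurements    # per-subject Lm, foci density, mean HU, T2 ratios
rep$tests           # exact pairwise Mann-Whitney + Kruskal-Wallis
rep$correlations    # cross-modality Spearman panel (HU~Lm, T2~Lm, ...)
```

A thin CLI over the same functions lives at `inst/cli/emphyquant.R`
(subcommands `run`, `simulate`, `lm`, `foci`, `ct`, `mri`, `stats`).

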