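---
title: "Methods: quantifying emphysema-like change from histology and live imaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying emphysema-like change from histology and live imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emphyquant)
```

# The measurement problem

Cigarette-smoke exposure models of emphysema in mice are read out through
four complementary quantities:

* **Mean linear intercept (Lm)** on H&E histology — the mean length of
  airspace chords cut by test lines; alveolar destruction enlarges airspaces
  and raises Lm.
* **Leukocyte infiltration foci** — clusters of more than 20 infiltrating
  leukocytes per 20 mm&sup2; of scored section, an index of parenchymal
  inflammation.
* **Mean lung density in Hounsfield units (HU)** from micro-CT —
  emphysematous lung holds more air, so its mean HU falls (becomes more
  negative).
* **T2-weighted MRI intensity ratios** — inflammation and fluid retention
  raise lung T2 signal; intensities are normalised by arm muscle in the same
  slice to cancel scanner gain.

`emphyquant` implements each readout as an explicit, parameterised
procedure, together with the exact small-sample nonparametric statistics
(n = 4–5 per group is typical) and a synthetic-data generator that produces
inputs with *known* ground truth so the whole chain is testable without any
animal data.

# Stereology: the chord-length estimator

The input is a binary tissue mask (`TRUE` = tissue) with a calibrated pixel
size; polarity is fixed at 255 = tissue on disk and inversion is an explicit
reader flag, never guessed. The estimator:

1. **Field selection** (`select_fields()`): candidate fields tile the
   section on a regular lattice with stride equal to the field size and a
   single seeded random offset (systematic uniform sampling). Fields
   intersecting the exclusion mask — bronchioles, vessels wider than
   50 µm, other non-airway structure, supplied as a mask because that
   judgement is made by a human, not this package — are discarded, and the
   requested number of fields is spread evenly over the survivors. The
   default is 5 fields per section over 3 sections per subject.
2. **Chord measurement** (`measure_chords()`): parallel test lines are laid
   across each field; maximal runs of airspace pixels along a line are
   chords. Runs touching the field border are discarded — they are
   right-censored lengths and keeping them biases Lm downward — and chords
   shorter than `min_chord_um` (default 10 µm) are dropped. Both horizontal
   and vertical line sets are measured to cancel orientation bias.
3. **Hierarchical averaging** (`compute_lm()`): field mean over pooled
   chords, section mean over field means, subject Lm over section means,
   all unweighted. Whether chord pooling or field averaging is used is
   rarely stated in practice; the unweighted hierarchy is this package's
   documented choice, and every intermediate level is returned so either
   convention can be recomputed.

Tunable parameters, defaults, and reasons:

| parameter | default | rationale |
|---|---|---|
| `line_spacing_um` | 50 µm | about one alveolar diameter: dense enough for stable field means, sparse enough that adjacent lines are weakly correlated |
| `min_chord_um` | 10 µm | excludes capillary-scale gaps and mask noise; the conventional threshold for this assay |
| `field_size_um` | 600 µm | approximates a 20×-objective capture |
| fields × sections | 5 × 3 | the usual sampling effort per subject |

At a line spacing of one pixel over a whole section the estimator degenerates
to an exhaustive run-length scan; this is both a test oracle (an independent
scan implementation must agree chord-for-chord) and the definition of the
ground truth recorded by the foam generator (`exhaustive_mean_chord()`).

# Synthetic alveolar tissue

Two phantom morphologies (`generate_alveolar_section()`):

* **`parallel_septa`** — vertical walls of thickness `septum_um` on a period
  `period_um`: every interior horizontal air chord is exactly
  `period_um − septum_um`, an analytic ground truth used to pin the
  estimator (period 50, septum 10 ⇒ Lm = 40 µm, exactly).
* **`voronoi_foam`** — a Voronoi tessellation whose boundary bands are
  septa. Seeds are a jittered-lattice point process: one seed per
  period-sized lattice cell, uniformly jittered by up to 0.45 cells. The
  jittered lattice was chosen over a homogeneous Poisson process because it
  bounds the nearest-neighbour search (making the generator fast and exactly
  reproducible in pure R) and because its hard-core-like regularity
  resembles alveolar packing better than a raw Poisson pattern, which
  produces degenerate sliver cells. A pixel is tissue when the difference
  between its distances to the second-nearest and nearest seeds is at most
  the septum width, which yields walls of approximately the requested
  thickness.

Airspace enlargement is modelled mechanistically: a fraction
`emphysema_fraction` of the shared walls (unordered pairs of adjacent cells)
is deleted. The deletion order is a fixed seeded permutation drawn after the
tessellation, so at a fixed seed larger fractions remove strict supersets of
walls — the true mean chord is monotone in the fraction by construction, and
matched-seed masks are nested. The foam's true mean chord has no closed
form, so it is established by the exhaustive 1-px chord scan of the entire
mask and recorded in the ground-truth record.

Default geometry (period 48 µm, septum 7 µm, 2 µm pixels) was calibrated
once so the intact foam reads Lm ≈ 34.5 µm — the scale reported for healthy
BALB/c lung — and `emphysema_fraction = 0.19` reads ≈ 42.6 µm, the ≈ 22%
enlargement typical of 12-week smoke exposure. Histology masks are
noise-free binary images: the package's boundary is the thresholded mask,
not H&E colour segmentation.

# Leukocyte foci

`detect_foci()` makes the visual counting rule operational: cells closer
than `linking_radius_um` are linked, connected components (single linkage)
are clusters, and a cluster is a focus when it has **at least 21** members —
the strict reading of "more than 20". No proximity rule accompanies the
visual procedure in practice, so the 25 µm default radius (about two
leukocyte diameters) is this package's stated reconstruction, exposed as a
parameter everywhere. Densities are `n_foci × 20 / section_area_mm2`, and
the subject value is the unweighted mean over its sections.

The neighbour search buckets points on a grid of cell size equal to the
radius and unions across adjacent buckets, so it examines only near pairs;
tests hold it to exact agreement with a naive all-pairs union-find.

The generator (`inject_leukocyte_foci()`) places focus centres by rejection
sampling with an enforced empty gap (default 150 µm, six linking radii)
between focus boundaries, then grows each focus by sequential attachment:
every cell lands 5–20 µm from an already-placed cell, inside the focus
disc. Attachment guarantees each focus is single-linkage connected at the
default radius *by construction* — uniform scatter in a disc does not — so
detected count equals injected count deterministically. Background cells
are a sparse Poisson scatter (default 2 cells/mm&sup2;), far too sparse to
assemble 21-member chains.

# CT densitometry

Raw scanner intensities are mapped to HU by two-point linear calibration,
`HU(v) = 1000 (v − water)/(water − air)`, anchored at a distilled-water
region (0 HU) and an air region (−1000 HU), then clamped to the
reconstruction range [−1000, 1000]. Water alone fixes only the offset; air
as the second anchor is the HU definition itself. The synthetic volumes
apply a seeded unknown affine transform (gain 0.5–2, offset ±200) to true
HU precisely so that calibration is a real, testable step — the procedure
is exactly invariant to any affine distortion of the raw scale.

`mean_hu()` averages HU over the supplied volume of interest — anatomical
landmarking is out of scope, the VOI arrives as a mask — optionally
intersected with a lung window (default [−900, −100] HU) that excludes
bone/soft tissue above and trachea-like pure air below. Published analyses
rarely state whether the averaged voxel set was threshold-restricted, so
both modes are provided (`lung_window = NULL` averages the full VOI).
Percentage changes from baseline week are computed on the raw signed
values; for a negative-valued HU series a density *decrease* (e.g. −357 →
−399.1 HU) is a *positive* percentage (+11.79%), since the baseline's sign
cancels.

# MRI ratios

`t2_ratio()` divides mean lung (and kidney, when the ROI is present)
intensity by mean arm-muscle intensity in the same slice. The ratio is
exactly invariant to global intensity scaling. The slice generator writes
labelled ellipse/rectangle ROIs at stated mean levels plus Gaussian noise;
at zero noise the round trip is exact (lung 318 / muscle 250 ⇒ 1.272, i.e.
27.2% above a lung-equals-muscle reference).

# Exact statistics

All tests condition on the observed midrank tie pattern and define the
two-sided p as `min(1, 2 × smaller one-sided tail)`, the convention of the
common biostatistics packages. Consequences worth knowing:

* Complete separation gives `p = 2 / choose(n1+n2, n1)`: 2/252 = .0079 at
  5 v 5, 2/70 = .0286 at 4 v 4, 2/126 = .0159 at 5 v 4; a single inverted
  pair at 5 v 4 (U = 1) gives 4/126 = .0317.
* The exact test is conservative: at 5 v 5 the attainable two-sided levels
  are 2k/252, so the realised type-I rate at α = .05 is exactly
  8/252 ≈ .0317, not .05. (The attainable level above it, 14/252 ≈ .0556,
  already exceeds α.)

`mann_whitney_exact()` enumerates all `choose(n1+n2, n1)` rank assignments
for total n ≤ 20 and falls back to the tie-corrected normal approximation
beyond. `wilcoxon_signed_rank_exact()` drops zero differences (reported),
and computes the exact sign-flip distribution over 2&#8319; patterns by
convolution over the doubled midranks — algebraically identical to literal
enumeration, at linear memory. `kruskal_wallis()` uses the tie-corrected H
with a χ&sup2; reference, with optional full enumeration for total n ≤ 10.
`spearman()` is the Pearson correlation of midranks with an exact
permutation p for n ≤ 9 (all n! permutations) and a t-approximation with
df = n − 2 beyond. Group descriptives are median and range, the reporting
convention at these sample sizes, and fold changes are ratios of group
medians.

# The synthetic cohort and pipeline

`study_design()` defaults mirror the modelled experiment: three groups
(fresh-air control, smoke-exposed, smoke-exposed with interventional
azithromycin), n = 5 each, imaging at weeks 0, 6, 8, 10, 12, terminal
histology with 3 sections and 5 fields per subject. Group effect parameters
are set to the magnitudes that characterise such a study: Lm 34.5 µm intact
vs ≈ +22% under smoke, recovered under treatment (period × 0.96, wall
removal off); lung HU falling from −357 at baseline toward −399.5 (smoke),
−384.9 (control), −377.3 (treated) at week 12; lung/muscle T2 ratio ≈ +27%
under smoke; focus densities near 1.1, 10.98 and 5.147 per 20 mm&sup2;.

A per-subject latent severity `z ~ N(0, 1)` perturbs all four modalities
coherently (wall-removal fraction +0.015 z, lattice period ×(1 + 0.02 z),
lung HU −4 z, T2 ×(1 + 0.03 z), focus density ×(1 + 0.25 z)), which is
what gives the cross-modality Spearman panel (HU~Lm negative, T2~Lm
positive, …) its sign in synthetic cohorts. No inter-mouse variance
components are available to copy from real data; these coefficients were
chosen once to make n = 4–5 group separations achievable at the stated
effect sizes, and are not fitted to any biology.

What the generator deliberately does **not** emulate: scanner physics
(ring artifacts, beam hardening, gating), H&E colour and staining
variability, anatomical landmark identification, irregular lobe boundaries,
and spatial heterogeneity of disease within a section. Passing recovery
tests therefore demonstrates that the *measurement procedures* are correct
and unbiased under their own assumptions — not that segmentation or
acquisition errors on real data would be benign.

`run_pipeline()` executes simulate → quantify (lm, foci, ct, mri) → stats
from a single `run_config()`, logs every effective parameter (silent
defaults are forbidden), writes per-stage CSVs plus a JSON report, and is
byte-reproducible at a fixed seed. Stages can be re-run individually on the
frozen CSVs; group comparisons and the correlation panel run at the final
imaging week by default. A thin command-line wrapper
(`inst/cli/emphyquant.R`) exposes `run`, `simulate`, `lm`, `foci`, `ct`,
`mri` and `stats` subcommands over these functions.

# Numerical choices and degenerate inputs

* Chord lengths are pixel-run counts × pixel size; geometry is exact when
  the period and septum are integer multiples of the pixel. A period under
  2 pixels is rejected as degenerate.
* Field selection falls back to fewer fields with a warning when the
  exclusion mask is too aggressive, and errors only when no clean field
  exists. Sections whose fields yield no chords are flagged
  (`undefined = TRUE`), never silently averaged.
* All-equal groups give p = 1 with a degenerate flag; zero-variance
  correlation inputs return an undefined flag rather than NaN.
* Every generator restores the caller's RNG state; determinism is
  seed-and-parameters only, and sub-seeds derived for subjects and
  timepoints stay below 2³¹.
* Exact-test tail comparisons use a 10⁻⁹ slack on midrank sums to absorb
  floating-point representation of half-integer ranks.

# Problem sizes used in the tests

The shipped tests exercise the full chain at reduced sizes chosen as the
package's own test design: foam masks of 1800 px (3.6 mm at 2 µm/px) with
15 fields of 700 µm for Lm recovery (20 seeds, error against the
exhaustive oracle under 5%), 900 px masks for the severity contrast, 100
synthetic sections for focus recovery, 16–32 voxel CT phantoms, and a
two-group, two-subject cohort for the end-to-end pipeline properties.
Subject-level Lm recovery uses fields several times the mean chord length;
with much smaller fields the border-discard rule visibly biases Lm
downward (discarded censored chords are preferentially long), which is the
main caveat to carry to real 20× captures of severely emphysematous tissue.

# Known limitations

* Lm here is the air-chord mean only; tissue-intercept variants and
  shrinkage corrections are out of scope.
* The focus definition is a geometric reconstruction of a visual count; on
  real slides the effective linking radius of a human observer is unknown
  and should be sensitivity-checked with the `linking_radius_um` parameter.
* The Kruskal–Wallis exact path enumerates only up to total n = 10; beyond
  that the χ² reference is used regardless of how small the groups are.
* Percentage-change sign conventions on negative series differ across
  published reports; this package always uses raw signed values and
  documents the consequence.
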