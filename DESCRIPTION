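Package: emphyquant
Title: Quantitative Imaging and Stereology Pipeline for Murine Emphysema Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reproducible quantification of emphysema-like change in mouse
    models from histology and live imaging: mean linear intercept (Lm)
    stereology by grid-overlay chord measurement on binary tissue masks,
    enumeration of leukocyte infiltration foci by single-linkage spatial
    clustering, Hounsfield-unit calibration and lung-density summarisation of
    micro-CT volumes, and T2-weighted MRI intensity ratios. Exact small-sample
    nonparametric statistics (Mann-Whitney, Wilcoxon signed rank,
    Kruskal-Wallis, Spearman) are computed by full enumeration. A synthetic
    cohort generator with analytically or exhaustively known ground truth makes
    every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tiff,
    RNifti,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
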