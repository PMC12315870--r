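Package: batchcal
Title: Calibration Testing for Single-Cell Batch-Correction Methods
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tests whether single-cell RNA-seq batch-correction methods are
    well calibrated: a dataset with no true batch effect is randomly split
    into two pseudobatches, a (pluggable) correction method is applied, and
    the artifacts introduced by correction are quantified at three stages of
    the standard workflow. Local structure is measured by a k-nearest-neighbor
    rank-displacement statistic, clustering by matched confusion matrices,
    batch-imbalance ratios and the Adjusted Rand Index, and differential
    expression by a two-part hurdle model with per-gene likelihood-ratio
    tests under Bonferroni correction. Includes a negative-binomial UMI count
    simulator with known cell-type structure, targeted batch-effect injection
    and batch downsampling as perturbation baselines, and built-in reference
    correctors (identity, location-scale, exact oracle inverse).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    igraph,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
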