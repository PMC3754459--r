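Package: vbmoverlap
Title: Voxel-Based Morphometry with Cluster Inference and Conjunction
    Overlap Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A mass-univariate voxel-based morphometry (VBM) pipeline for
    factorial studies of brain tissue volume: tissue-map preprocessing
    (analysis masking, tissue-specific rescaling, Gaussian smoothing),
    voxel-wise general linear models with t contrasts and residual-based
    smoothness estimation, Gaussian-random-field cluster-level inference
    with topological false discovery rate control, and a directional
    conjunction-overlap statistic across a ladder of voxel-level thresholds
    calibrated against a smoothness-matched Monte Carlo null. Includes a
    synthetic-cohort generator with plantable sex, diagnosis, interaction
    and age effect fields so the whole pipeline is testable end to end, and
    summary-statistic utilities (cell-means ANOVA, Pillai MANOVA, two-sample
    t, digit-ratio correlation and interaction regression) for group-level
    volumetrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    igraph,
    car,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
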