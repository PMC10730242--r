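Package: endotyper
Title: Outcome-Guided Endotyping of Subclinical Carotid Atherosclerosis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An outcome-guided machine-learning pipeline for discovering and
    validating endotypes of subclinical carotid atherosclerosis in tabular
    cohort data. Provides a seeded synthetic cohort generator with latent
    classes, correlated biomarker blocks, carotid ultrasound measures and
    censored time-to-event outcomes; Z-standardization and ultrasound
    summary derivation; a supervised encoder multilayer perceptron that
    learns carotid intima-media thickness related representations;
    hierarchical clustering with silhouette-based selection of the number
    of endotypes; an ensemble stacking classifier for endotype replication
    in new cohorts; permutation Shapley attributions; weighted correlation
    network analysis (soft thresholding, topological overlap, tree-cut
    module detection); linear and Cox association models with diagnostics;
    and censoring-adjusted net reclassification improvement with bootstrap
    confidence intervals against SCORE2-style risk categories.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    cluster,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    nnet,
    ranger,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    xgboost,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
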