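Package: molgcn
Title: Graph Convolutional QSAR Models for Quantitative Activity Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative structure-activity (pIC50) modelling with graph
    convolutional neural networks. Provides ChEMBL-style activity-table
    curation (filtering, structure standardization, p-activity transform,
    duplicate aggregation), seeded two-stage train/validation/test splitting,
    75-bit per-atom molecular-graph featurization, a graph convolutional
    regressor trained with Adam under an epoch-block stopping rule and
    selected by the 2R2_MAE validation metric, Bayesian (Gaussian-process
    expected-improvement) hyperparameter search with tiered retention rules,
    unweighted model ensembling, Murcko carbon-skeleton scaffold-diversity
    diagnostics (Shannon entropy and Kullback-Leibler divergence over
    size-ordered scaffold bins), virtual-screening filters, and a synthetic
    activity-table generator with a planted additive structure-activity
    relationship for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ChemmineR,
    ChemmineOB,
    Rcpp,
    graphics,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
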