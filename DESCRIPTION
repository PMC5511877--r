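Package: TNTsuppress
Title: Brain-Behavior Analysis of Intrusive-Memory Suppression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis machinery for Think/No-Think (TNT) studies of parallel
    memory and emotion suppression. Provides trial-level intrusion scoring and
    norm-adjusted affect-suppression measures with robust MAD trimming, skipped
    (bivariate-outlier-resistant) correlations with percentile-bootstrap
    confidence intervals and an item-split resampling control, behavioral
    partial least squares (PLS) with permutation tests and bootstrap standard
    ratios, peak-seeded contiguous ROI selection on statistic maps, and a
    desk-scale bilinear dynamic causal modelling (DCM) engine with
    variational-Laplace evidence, random-effects Bayesian model selection,
    family inference, Bayesian model averaging, and coupling bootstraps. A
    synthetic-cohort generator with known ground truth makes every stage
    testable without access to subject data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    MASS,
    jsonlite,
    Rcpp,
    S4Vectors,
    SummarizedExperiment
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
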