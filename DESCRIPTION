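Package: qsarmix
Title: QSAR Modelling with Mixed-Kernel Support Vector Regression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative structure-activity relationship (QSAR) modelling
    pipeline for enzyme-inhibition data, built around an epsilon-support-vector
    regression with a composite (RBF + polynomial + linear) kernel. Provides
    descriptor pre-filtering and stepwise multilinear descriptor selection by
    the Fisher criterion, gradient-boosted-tree feature importance with a
    cumulative-importance cutoff, random-forest and single-kernel SVR baseline
    models, a mixed integer/real particle swarm optimizer with linearly
    decreasing inertia for hyperparameter tuning, leave-one-out
    cross-validation, and a synthetic descriptor-matrix generator for
    end-to-end testing without proprietary descriptor software.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    ranger,
    xgboost,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    kernlab,
    e1071,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
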