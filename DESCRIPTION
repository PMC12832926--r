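Package: cardiopso
Title: Robust Preprocessing and Improved Particle Swarm Optimization for
    Heart-Disease Diagnosis Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Toolkit for building clinical heart-disease classifiers on the
    14-attribute UCI-style tabular schema. Provides a robust preprocessing
    pipeline (forward-fill imputation of missing values, exact-duplicate
    removal, interquartile-range outlier detection with median imputation,
    and median/IQR robust scaling), a clinical diagnostic-accuracy metric
    panel including likelihood ratios and the diagnostic odds ratio, an
    improved particle swarm optimizer with a linearly decaying inertia
    weight and Gaussian mutation for joint feature selection and classifier
    hyperparameter tuning, a synthetic-cohort generator with planted signal
    and injectable data pathologies, and an experiment harness for split
    grids, ablations, paired t-tests and feature-selection frequency
    analysis.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    zoo,
    jsonlite,
    e1071,
    glmnet,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    MASS,
    pROC,
    yaml,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
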