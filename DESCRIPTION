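Package: molUQ
Title: Uncertainty Quantification for Molecular Property Predictions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Model-agnostic uncertainty estimation for machine-learning
    predictions of mass-spectrometry-related molecular properties
    (gas-chromatographic retention indices, liquid-chromatography retention
    times, collision cross-sections). For every prediction the package
    computes applicability-domain features: nearest-training-set molecular
    similarity (Tanimoto and cosine similarity of circular count
    fingerprints, Euclidean distance in a PCA-reduced descriptor space,
    maximum-common-substructure similarity), k-means chemical-space cluster
    membership with per-cluster error statistics, and the spread of the
    predictions of an ensemble of models. A second-stage meta-classifier
    (logistic regression or gradient boosting) turns the features into the
    probability that a prediction falls into the worst error fraction, so
    unreliable predictions can be flagged before they are used for
    identification. Includes a synthetic-data generator emulating ensembles
    with Laplace-tailed, difficulty-driven errors for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    igraph,
    jsonlite,
    yaml,
    xgboost,
    ChemmineR,
    ChemmineOB
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS,
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
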