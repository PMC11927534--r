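Package: hdestack
Title: Diversity-Driven Stacking Ensembles with Hybrid Differential
    Evolution for Multimodal Variety Identification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds interpretable stacking ensembles for crop variety
    identification from fused morphological and hyperspectral feature
    tables. Candidate classifiers are ranked by a comprehensive score
    blending pairwise diversity measures (disagreement, Q-statistic,
    kappa, correlation) with macro performance metrics; hyperparameters
    of the selected base learners are tuned by a hybrid differential
    evolution optimizer with stage-scheduled multi-strategy mutation and
    convergence/diversity-adaptive control parameters. Includes
    chemometric spectral preprocessing (Savitzky-Golay smoothing,
    min-max normalization), wavelength selection by successive
    projections (SPA), competitive adaptive reweighted sampling (CARS)
    and bootstrap soft shrinkage (BOSS), a synthetic multimodal seed
    data generator for end-to-end testing, and weighted Shapley-value
    explanations of the fitted ensemble.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    signal,
    nnet,
    rpart,
    e1071,
    kernlab,
    caret,
    randomForest,
    mixOmics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    class
Config/testthat/edition: 3
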