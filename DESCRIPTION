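Package: drcheck
Title: Data Representativeness Criterion for Predicting Classifier
    Generalization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies how representative a training data set is of a new
    unseen data set before a supervised classifier is deployed. Implements the
    proxy A-distance (the held-out error of a domain classifier mapped onto
    [0, 2]) and the Data Representativeness Criterion (DRC), a ratio of
    Kullback-Leibler divergences between the beta distribution fitted to
    pooled domain-classification probabilities and two fixed benchmark priors.
    Includes the full patch-based image pipeline used for magnetic resonance
    imaging (patch extraction under a brain mask, per-scan intensity
    normalization), a synthetic multi-scanner T1-weighted phantom simulator
    for fully reproducible experiments, replication and stability sweeps, and
    a surrogate tissue-classification experiment exhibiting the turning point
    at which training data stops helping on unseen data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    png,
    purrr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    fitdistrplus,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
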