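Package: dlmm
Title: One-Shot Distributed Linear Mixed Models from Aggregated Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Fits linear mixed models with site-level random effects across
    horizontally partitioned multi-site data without pooling individual
    records. Each site reduces its data once to four aggregated objects
    (the cross-products X'X, X'y, y'y and the sample size); the coordinator
    reconstructs the exact pooled maximum-likelihood and restricted
    maximum-likelihood profile objectives from those objects alone via the
    Woodbury matrix identity and the matrix determinant lemma, so estimates,
    standard errors (model-based and sandwich), likelihood-ratio selection
    of variance components with the boundary 50:50 chi-square mixture null,
    and per-site best linear unbiased predictors with prediction intervals
    are numerically identical to the pooled-data analysis. Includes a
    multi-site data simulator, a dense pooled-data reference implementation
    used to verify the lossless property, a sparse-cell privacy audit for
    shared aggregates, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    tibble,
    dplyr,
    purrr,
    rlang,
    readr,
    generics,
    ggplot2
Suggests:
    lme4,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
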