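Package: netstage
Title: Stage-Specific Net Survival from Registry Data with Multiply Imputed Stage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating long-term stage-specific marginal relative
    survival from cancer-registry data when historical stage at diagnosis is
    largely missing. Implements period analysis with delayed entry and a
    pre-window, multiple imputation of stage under a multinomial model with
    cumulative-hazard covariates, stage-stratified flexible parametric
    excess-hazard models on the log cumulative-hazard scale, regression
    standardisation to a reference diagnosis year, Rubin's-rules pooling, and
    non-parametric Pohar-Perme net survival for model-free validation. A
    synthetic registry generator with known stage-specific excess hazards and
    a configurable stage-missingness mechanism makes the whole pipeline
    testable without access to registry extracts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    nnet,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    flexsurv,
    pracma,
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
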