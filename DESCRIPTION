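Package: omatraj
Title: Longitudinal Treatment-Response Phenotyping for Omalizumab in
    Antihistamine-Refractory Chronic Urticaria
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to phenotype longitudinal treatment response to omalizumab
    add-on therapy in antihistamine-refractory chronic urticaria from
    prescription records. Includes a synthetic electronic-medical-record
    cohort generator with known latent responder classes, medication-burden
    scoring in loratadine/prednisolone equivalents, a rule-based response
    classifier evaluated on a fixed assessment grid, shape-respecting
    trajectory clustering built on the discrete Frechet distance, time to
    first complete response with Kaplan-Meier and log-rank statistics, Fleiss
    kappa agreement between cluster and responder-timing labels, and
    logit-link GLM screening of baseline laboratory predictors with odds
    ratios and Wald confidence intervals. All user-facing functions take and
    return tibbles so stages chain with the pipe; an end-to-end pipeline
    runner writes reproducible CSV/JSON artifacts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
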