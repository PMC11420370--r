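Package: cchcox
Title: Cox Model Inference for Stratified Case-Cohort Designs
Version: 0.1.0
Authors@R: person("cchcox", "maintainers", email = "maintainers@example.org",
    role = c("aut", "cre"))
Description: Estimation and influence-function based variance estimation for
    Cox proportional hazards models fitted to stratified (or unstratified)
    case-cohort data. Provides weighted partial-likelihood estimation of
    log-relative hazards, the Breslow cumulative baseline hazard and
    covariate-specific pure risk; design-based two-phase variance estimators
    with joint inclusion weights for without-replacement subcohort sampling;
    survey weight calibration (raking) against auxiliary variables built from
    imputed covariates; inverse-probability-weighted analysis of missing
    phase-two covariates treated as a third sampling phase with estimated
    missingness weights; a synthetic cohort generator and a simulation study
    runner comparing designs; and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    survival,
    withr
Config/testthat/edition: 3
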