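Package: gliotwin
Title: Predictive Digital Twins for Risk-Aware Radiotherapy Planning in
    High-Grade Glioma
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds patient-specific predictive digital twins for high-grade
    glioma radiotherapy planning. Couples a logistic tumor-growth model with
    discrete radiotherapy and chemotherapy kill events (linear-quadratic cell
    survival), Bayesian calibration of the patient-specific parameters from
    sparse noisy tumor-burden observations via adaptive Markov chain Monte
    Carlo, alpha-superquantile (conditional value-at-risk) estimation of time
    to progression, risk-based optimization under uncertainty of weekly
    radiotherapy dose schedules with a total-dose constraint, and cohort-level
    Kaplan-Meier/logrank survival analysis over an in-silico patient cohort.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
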