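Package: eldertrans
Title: Disability Transitions and Health Expectancies in Elderly Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Continuous-time multistate Markov modelling of disability
    dynamics in elderly panel cohorts observed at irregular survey waves.
    Provides BADL/IADL disability classification into no/mild/severe living
    states plus death, an interval-censored panel likelihood with exact
    death times and unknown state at death, maximum-likelihood fitting with
    covariate (age, sex, urban/rural region) effects on transition
    intensities, annual transition probabilities, multistate life tables
    and health expectancies with percentile-bootstrap confidence intervals,
    Cox proportional-hazards models of disability onset with nested
    adjustment sets and missing-category dummies, predictive-mean-matching
    multiple imputation, and a synthetic cohort generator with known ground
    truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    Matrix,
    survival,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
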