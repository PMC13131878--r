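Package: tgitte
Title: Tumor Growth Inhibition and Time-to-Event Modeling for Preclinical
    Xenograft Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-stage translational modeling framework linking drug
    exposure, tumor growth dynamics, and survival in mouse xenograft
    efficacy studies. Stage one fits a population (nonlinear mixed-effects)
    Simeoni tumor-growth-inhibition model with a plasma-concentration-driven
    linear kill term, driven by a one-compartment bolus pharmacokinetic
    model; stage two fits a parametric log-logistic time-to-event model
    whose scale parameter depends on the individual empirical-Bayes growth
    rates and on regimen-level average concentration. Includes forward
    simulation of complete synthetic xenograft studies, Kaplan-Meier visual
    predictive checks, subject-resampling bootstrap, and tidy accessors for
    all fitted objects.
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
    jsonlite,
    pracma,
    purrr,
    Rcpp,
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
    deSolve,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
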