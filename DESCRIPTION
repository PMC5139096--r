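Package: ovascreen
Title: Cost-Effectiveness Modelling of Ovarian Cancer Screening
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A model-based economic evaluation pipeline for population
    screening for ovarian cancer among postmenopausal women, built around
    the three-arm UKCTOCS trial design (no screening, multimodal screening
    and ultrasound screening). Provides a synthetic three-arm trial
    simulator with known truth, reconstruction of pseudo individual patient
    data from digitized Kaplan-Meier curves and numbers-at-risk tables
    (the Guyot algorithm), Royston-Parmar spline models with time-varying
    hazard ratios and standard parametric survival fits selected by BIC,
    lifetime extrapolation of hazards and hazard ratios by damped-trend
    exponential smoothing with an optional model-discrepancy adjustment,
    a six-state annual-cycle Markov cohort model with half-cycle correction
    and discounting, probabilistic sensitivity analysis with
    cost-effectiveness acceptability curves, and regression-based expected
    value of (partial) perfect information.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    survival,
    flexsurv,
    mgcv,
    stats,
    graphics,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
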