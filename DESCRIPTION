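Package: cvdscore
Title: SCORE-Style Weibull Proportional-Hazards Modelling of Fatal
    Cardiovascular Risk
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits sex-stratified Weibull proportional-hazards models on the
    age timescale with left truncation at baseline age, as used by the
    European SCORE methodology for predicting fatal cardiovascular disease.
    Computes absolute risk over arbitrary horizons (10, 20, 30 years),
    renders SCORE-style risk charts over sex, smoking, age, systolic blood
    pressure and a blood marker (fasting glucose or total cholesterol), and
    compares competing risk models with censoring-aware metrics: the IPCW
    Brier score (with cross-validation), the time-dependent AUC at a horizon,
    the integrated discrimination improvement with a Wald test, and a paired
    permutation test for Brier-score differences.  A synthetic-cohort
    generator emulating the Swiss NRP1A baseline structure makes the whole
    pipeline runnable and testable without access to the original data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    survival,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    flexsurv,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
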