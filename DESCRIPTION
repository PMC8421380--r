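Package: prvscreen
Title: Pulse Rate Variability Statistics and Diagnostic Evaluation for
    Atrial Fibrillation Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computes pulse rate variability (PRV) statistics (standardised
    average real variability, RMSSD, standard deviation, coefficient of
    variation, relative range and irregular pulse percentage) from short
    beat-interval recordings, with the beat-exclusion pre-filter used in
    opportunistic atrial fibrillation (AF) screening during blood pressure
    measurement.  Provides threshold and combination classification rules
    (including fusion with a single-lead rhythm-monitor label), contingency
    analysis of categorical device output under explicit policies for
    unreadable recordings, and a diagnostic evaluation battery: ROC curves
    with AUC and DeLong confidence intervals, repeated stratified k-fold
    cross-validation, decision curve analysis (net benefit), precision-recall
    curves and prevalence-adjusted positive predictive value.  A synthetic
    cohort generator reproduces the statistical structure of a primary-care
    AF screening population so the full pipeline can be exercised end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    pROC,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
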