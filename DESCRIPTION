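Package: blastdose
Title: Dosimetry and Dose-Response Analysis for Larval Zebrafish Blast
    Traumatic Brain Injury
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Converts raw pressure-transducer recordings from a weight-drop
    blast traumatic brain injury (TBI) rig into calibrated pressure traces
    (kPa), segments traces into pressure waves and computes per-drop dose
    metrics (maximal pressure, wave counts, inter-wave intervals, replicate
    RSD), quantifies post-TBI behavioural phenotypes from plate-tracking
    activity exports (high-activity seizure-candidate bouts, one-minute
    inactivity bouts, fin-poke stimulus response), and fits the dose-response
    models linking phenotypes to injury dose: simple linear regression,
    simple and multiple logistic regression with per-unit odds-ratio scaling
    and ROC AUC, and one-way ANOVA with Dunnett comparisons against a shared
    control. A synthetic-data module generates bouncing-weight pressure
    traces, dose-structured activity traces and Bernoulli phenotype tables
    so the whole pipeline can be exercised without animals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    multcomp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    pROC
Config/testthat/edition: 3
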