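Package: ripperr
Title: Interpretable Rule Induction for Clinical Risk Screening
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Sequential-covering rule induction in the RIPPER family for
    tabular clinical data: FOIL-gain rule growth, reduced-error pruning on
    a held-out prune set, minimum-description-length (MDL) stopping and
    rule-set optimization, and multiclass decision-list training with a
    default rule. Ships a static context-aware clinical screening rule set
    over banded physiological attributes (cholesterol, blood pressure,
    thallium scan, fluoroscopy vessel count, ...), confusion-matrix
    evaluation metrics with stratified cross-validation, a synthetic
    planted-rule data generator for testing, and a command-line interface
    for train/predict/evaluate/screen/simulate workflows.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
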