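Package: dispatchtriage
Title: Cost-Sensitive CHAID Decision Trees for Ambulance Dispatch Triage
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Grows Chi-square Automatic Interaction Detector (CHAID)
    decision trees over motor-vehicle-crash characteristics and Medical
    Priority Dispatch System (MPDS) Protocol-29 codes to predict whether an
    incident needs a lights-and-sirens ambulance response. Implements
    chi-square category merging with Bonferroni-adjusted split selection,
    cost-sensitive leaf classification, incremental misclassification
    cost-ratio sweeps, over/under-triage rates (one minus positive/negative
    predictive value) and model selection against the American College of
    Surgeons Committee on Trauma field-triage benchmark. Ships embedded
    cohort marginal tables and a seeded synthetic-data generator
    (fixture-faithful, planted-tree and null modes) for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
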