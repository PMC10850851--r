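Package: ddst
Title: Decision-Supported Delirium Screening with the CAM Algorithm
Version: 0.1.0
Authors@R:
    person("ddst", "maintainers", email = "ddst@example.org", role = c("aut", "cre"))
Description: An adaptive, decision-supported implementation of a 22-item
    bedside delirium screening instrument built on the Confusion Assessment
    Method (CAM) diagnostic algorithm: a configurable item bank with
    reminders and interpretation cues, an assessment engine with automatic
    logic jumps and early stopping, a longitudinal patient-record store that
    auto-derives the acute-change-from-baseline item, a synthetic
    randomized-crossover usability-trial generator, and the accompanying
    comparison statistics (Fisher exact and Yates-corrected chi-square
    completion-rate tests, paired Wilcoxon signed-rank domain comparisons,
    order-effect ANOVA, and sample-size planning with attrition inflation).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
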