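Package: mrpscore
Title: Scoring, Design and Simulation for Massive-Report Patch-Discrimination Experiments
Version: 0.1.0
Authors@R: person("MRP", "Maintainers", email = "mrpscore@example.org", role = c("aut", "cre"))
Description: Tools for the massive report paradigm (MRP) in visual
    psychophysics: confidence-rating signal detection scoring
    (criterion-sweep Type 1 and Type 2 ROC curves and non-parametric AUC),
    transformed decision-by-confidence statistics and per-image-pair
    classification, experiment design planning (3x3 grid patching, probe
    schedules, null-patch allocation, catch-trial exclusion thresholds),
    natural-scene image statistics (change-region size, Weibull contrast
    scale), and a seeded rating-model simulator with exact ground-truth
    AUC so every analysis stage is testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    png,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
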