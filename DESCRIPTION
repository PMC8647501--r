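Package: dyncal
Title: Dynamic Updating Strategies for Clinical Prediction Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sequential ("dynamic") updating of logistic clinical prediction
    models over incident quarter-cohorts. Implements five update strategies --
    never update, closed testing selection among candidate updates, always
    recalibrate the intercept, always recalibrate the intercept and slope, and
    always refit (model revision) -- under configurable update intervals and
    sliding windows, together with an evaluation suite (Brier score, C-statistic,
    Hosmer-Lemeshow, logistic calibration intercept and slope, pairwise Wilcoxon
    signed-rank comparisons) and a synthetic drifting-cohort generator emulating
    the structure of transplant-registry quarter-cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
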