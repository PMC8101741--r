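Package: cycleshift
Title: Counterfactual Poisson Models for Shifts in Crowdsourced Outdoor
    Activity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies shifts in outdoor activity from crowdsourced
    fitness-app segment counts. Fits per-segment, per-calendar-month
    Poisson generalised linear models on pre-shock years (year trend,
    sunshine hours, and their interaction as candidate predictors),
    selects among the candidate forms by Akaike's Information Criterion,
    predicts the expected (counterfactual) activity for target months,
    and estimates observed-versus-expected median and percent
    differences with bias-corrected and accelerated (BCa) bootstrap
    confidence intervals, stratified by urban and rural segments.
    Includes a synthetic segment-count generator that emulates the
    structure of fitness-app leaderboard data joined with weather-station
    sunshine hours, so the full pipeline can be exercised and validated
    without proprietary inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    boot,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
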