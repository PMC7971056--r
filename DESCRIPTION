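Package: searchcontrast
Title: Estimate-then-Predict Modelling of Visual Search Efficiency
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the estimate-then-predict analysis of visual search
    reaction times. Fits logarithmic search-efficiency slopes (D, in ms per
    ln-unit of total set size) from trial-level data, converts them to
    target-distractor contrast scores, combines single-feature contrasts under
    competing rules (best-feature guidance, orthogonal/Euclidean combination,
    collinear/city-block integration, and a reciprocal-of-RT regression), and
    adjudicates between the rules with R-squared, Gaussian AIC, AIC relative
    likelihoods, prediction-error statistics and margin-of-error coverage.
    Includes a synthetic-cohort generator that emulates the homogeneous-display
    search design (13 conditions x 48 repetitions, distractor set sizes 0, 1,
    4, 9, 19, a 5-second response deadline, and sequential participant
    screening), so every stage of the pipeline is testable end to end with
    recorded ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
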