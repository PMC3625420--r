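Package: beepsych
Title: Psychometric Analysis of Sugar-Concentration Discrimination in Foraging Bees
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for psychophysical analysis of two-alternative free-choice
    foraging experiments, built around the three-parameter Weibull psychometric
    function (threshold, slope at threshold, lapse rate) on a relative-intensity
    (Weber-fraction-like) stimulus scale. Provides Bayesian posterior estimation
    of psychometric parameters from binomial choice counts by adaptive Metropolis
    sampling with a deterministic grid-integration oracle for validation;
    reduction of time-stamped flower-visitation event logs to daily choice
    responses, including plateau filtering, reversal-pair pooling,
    marked/unmarked concordance, non-reward and sequential (win-stay/lose-shift)
    analyses, and learning curves; a data-pooling simulation demonstrating
    slope underestimation when responses are averaged across individuals with
    heterogeneous thresholds; and a synthetic RFID-style visitation-stream
    generator for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    coda,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    readr,
    jsonlite,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
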