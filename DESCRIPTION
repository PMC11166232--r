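Package: patternshift
Title: Dynamic Complexity and Pattern Transition Detection for Daily
    Process Monitoring Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Nonlinear time-series analysis for daily self-rating data from
    psychotherapy process monitoring. Computes the dynamic complexity
    statistic (the product of a fluctuation and a distribution measure in a
    sliding window), surrogate-based significance masks and complexity
    resonance diagrams, significant critical-instability periods, and a
    pattern transition detection algorithm that pools six change points
    (mean, variance and trend of the raw series, plus mean changes of the
    dynamic-complexity series, recurrence-plot lines and time-frequency
    rows) into a transition day with a probability and a surrogate p value.
    Includes a synthetic generator for questionnaire-like multichannel
    series with planted regimes, instability windows and coupled diary
    category timelines, and reporting utilities that render the standard
    diagrams with machine-readable companions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    zoo,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
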