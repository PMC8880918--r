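Package: fuzzyslim
Title: Fuzzy Success Likelihood Index Method for Medication Error Probability
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies human error probability in hospital medication
    processes with a fuzzy extension of the Success Likelihood Index
    Methodology (SLIM). Expert-panel importance judgments, expressed as
    linguistic terms backed by triangular or trapezoidal fuzzy numbers, are
    aggregated with the similarity aggregation method (SAM) and defuzzified
    by the Chen-Hwang max-min scores to weight performance shaping factor
    (PSF) categories; factor weights within each category come from Chang's
    extent-analysis fuzzy analytic hierarchy process. Per-subtask PSF
    ratings on a 1-9 scale are combined into a Success Likelihood Index and
    mapped to a human error probability through a log-linear calibration.
    Ships an emergency-department case study (taxonomy of 17 factors in 3
    categories, a 31-subtask hierarchical task analysis, and its rating
    sheet), seeded synthetic generators for every input, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
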