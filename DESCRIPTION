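Package: ntaquant
Title: Semi-Quantification of Nontarget LC-ESI-HRMS Feature Tables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Converts peak areas in aligned nontarget LC-ESI-HRMS feature
    tables to concentration estimates with quantified uncertainty.
    Calibration gradients from authentic standards are pooled into
    retention-time windows; unknown compounds eluting in a window are scaled
    by the window's median gradient, with an uncertainty envelope from the
    quartile, minimum and maximum gradients. Includes the surrounding feature
    post-processing (elemental-ratio formula filtering, three-step blank
    subtraction, duplicate removal, polarity merging), validation metrics
    (prediction-error ratios, factor-of-k coverage, matrix effect, spike
    recovery), class-resolved compositional summaries, and a synthetic
    fixture generator for end-to-end testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
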