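Package: esnorms
Title: Equivalent Score Norms for Neuropsychological Tests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Norming and standardization of neuropsychological test scores with
    the Equivalent Score (ES) method. Computes exact non-parametric one-sided
    lower tolerance limits (outer and inner) from the Beta distribution of
    order statistics, partitions the rank range between the outer tolerance
    limit and the median into the five-point ES scale via a z-deviate based
    procedure, performs the regression-based demographic adjustment of raw
    scores (predictor screening, transform search, Bonferroni-corrected
    stepwise selection), applies conservative tied-rank corrections, and
    assembles the clinical norm table (cut-off, gray area, ES 0-4 adjusted
    score ranges). Includes a synthetic normative-sample generator and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
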