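Package: cwitnorms
Title: Regression-Based Normative Data for the D-KEFS Color-Word Interference Test
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and applies demographically adjusted, regression-based
    norms for the four subtests of the Delis-Kaplan Executive Function System
    Color-Word Interference Test (CWIT; a Stroop variant). Completion times
    are normalized to scaled scores (mean 10, SD 3) through percentile-rank
    conversion tables, regressed on polynomial age, education and sex terms
    with hierarchy-respecting stepwise simplification, and individual raw
    scores are converted to demographically adjusted Z- and T-scores.
    Includes the published Norwegian normative equations and conversion
    tables, cumulative error-count norms, tools to audit external norm sets
    (maladjustment regression, paired comparisons, low-score base rates),
    test-retest stability via intraclass correlations and reliable change
    indices, seemingly-unrelated-regression tests of coefficient equality,
    and a synthetic-cohort generator that reproduces the normative sample's
    demographic and effect structure for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
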