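Package: rtrole
Title: Determine the Therapeutic Role of Radiotherapy from Administrative
    Treatment Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Classifies daily radiotherapy treatment records as curative or
    palliative from routinely captured treatment parameters (dose per
    fraction, irradiated body region, primary disease site and days elapsed
    since the first treatment).  Grows binary chi-square recursive
    partitioning trees (a CHAID-style inducer with Bonferroni-adjusted
    split selection), handles missing predictors through a ranked cascade
    of reduced-variable trees, extracts tree paths as mutually exclusive
    human-readable classification rules, and provides internal-validation
    and stratified-audit machinery (expansion-weighted sensitivity,
    specificity and population misclassification rates with confidence
    intervals).  A synthetic record generator with configurable regimens,
    per-variable missingness and intent-label noise makes every step
    testable without access to confidential administrative data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
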