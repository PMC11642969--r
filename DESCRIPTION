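Package: paleosize
Title: Body-Size Turnover Analysis for Regional Extinction Events
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Tools for analysing body-size change in faunas across
    extinction-recovery ("turnover") events. Summarizes specimen-level
    shell measurements into species- and clade-level size tables,
    classifies post-extinction faunas as larger, smaller, or unchanged
    relative to a bootstrap non-selective-turnover null using a central
    confidence window, runs ancestor-descendant lineage comparisons
    (pooled, Welch, and permutation two-sample t-tests with Bonferroni
    correction), and generates synthetic faunas with size-biased survival
    and shifted origination for calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
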