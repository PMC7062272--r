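Package: sgains
Title: Identify Sudden Gains and Losses in Longitudinal Outcome Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to identify sudden gains and sudden losses -- large,
    stable session-to-session changes -- in repeated-measures outcome data
    such as weekly symptom questionnaires. Implements the classic
    three-criteria definition (absolute change cutoff, percentage change,
    and a pooled standard deviation stability test), Reliable Change Index
    based cutoff derivation, missing-data-aware adjusted critical values,
    construction of one-row-per-gain and one-row-per-person analysis
    datasets including reversal classification, extraction of secondary
    measure scores around each gain, descriptive summaries, plot-ready
    aggregates, and a seedable simulator of demo-like datasets with planted
    gains and known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    withr,
    tibble,
    dplyr,
    tidyr,
    rlang,
    readr,
    haven,
    readxl,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
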