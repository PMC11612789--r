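Package: shrewvoc
Title: Vocal Repertoire Analysis for Etruscan Shrew Ultrasonic Calls
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of the vocal repertoire of the Etruscan
    shrew (Suncus etruscus) and similar high-frequency callers: detection of
    call units in 192-200 kHz recordings, extraction of 22 time-, tonality-,
    source- and filter-related acoustic parameters, UMAP pre-processing and
    fuzzy c-means soft clustering with typicality-coefficient gradation
    analysis, voiced-percentage based assignment of discrete and graded call
    types (scream, screech, screech-scream, chirp), alignment of calls to
    ethogram behavior annotations, and call-rate mixed models with backward
    elimination. Ships a synthetic-call generator with known ground truth so
    the whole pipeline is testable without field recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    readr,
    rlang,
    withr,
    uwot,
    lme4,
    lmerTest,
    car,
    emmeans,
    jsonlite,
    yaml,
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    e1071,
    mclust,
    optparse
Config/testthat/edition: 3
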