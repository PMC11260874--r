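Package: foragecam
Title: Camera-Trap Foraging Analysis for Marked Butterflies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for motion-triggered camera records of
    individually marked butterflies visiting flower stations in an
    insectary. Parses and validates annotation tables into canonical
    visit records, estimates daily activity densities and pairwise
    coefficients of temporal overlap, segments visit streams into
    feeding bouts with a configurable gap threshold, tests each
    individual's station use against a uniform random-foraging null
    (asymptotic or Monte-Carlo chi-squared), and quantifies route
    repeatability with recurrence-based determinism (DET). Includes an
    agent-based generator of synthetic visitation datasets with ground
    truth, so every stage of the pipeline can be validated against
    known foraging strategies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
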