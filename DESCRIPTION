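Package: wordia
Title: Intersubjective Agreement Analysis for Free-Report Psychophysics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies how specifically freely reported words describe a
    briefly presented image using an intersubjective agreement (IA) index:
    a signal-detection AUC that compares a word's report frequency on its
    target image against its baseline report frequency across all other
    images, averaged over the participants who reported it. Includes a
    deterministic cleaning pipeline for typed verbal reports (within-trial
    deduplication, case folding, dictionary spell correction,
    table-driven lemmatization), per-image IA summaries and
    rarely-reported-word accounting, a sum-of-squared-error consistency
    statistic for image pairs with a shuffled-pair bootstrap null,
    confidence-IA correlation analyses, and a synthetic free-report
    generator that emulates the full blocked study design for parameter
    recovery and testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
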