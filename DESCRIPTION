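Package: spliceshift
Title: Screening and Characterising Splicing-Factor-Regulated Alternative Splicing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for identifying splicing-factor-regulated
    alternative-splicing events from inclusion/exclusion junction read counts.
    Quantifies percent-spliced-in (PSI), screens events between a knockdown and
    a control condition with Fisher's exact test and Benjamini-Hochberg FDR
    control, discovers GA-rich candidate binding hexamers with positional
    (cassette exon versus flanking constitutive exon) enrichment, elicits a
    position weight matrix motif by expectation-maximisation, quantifies
    minigene splice switching as an inclusion/exclusion index, and stratifies
    survival cohorts by a combined PSI + expression median-cutoff risk score
    with Kaplan-Meier estimation and a log-rank test. Includes a synthetic-data
    generator that emulates the RNA-seq-derived inputs of such a study so the
    whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    survival,
    jsonlite,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
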