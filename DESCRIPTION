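Package: stromanet
Title: Network Enrichment Analysis of Fibroblast Transcriptome Responses to
    Cancer Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis workflow for transcriptomes of fibroblasts confronted
    with cancer cells in co-culture. Implements network enrichment analysis
    (NEA) of altered gene sets against functional gene sets on a global
    functional-coupling network, using a chi-squared statistic on observed
    versus configuration-model expected cross-links, with a degree-preserving
    edge-swap randomization oracle; paired and independent differential
    expression with an absent-gene filter and Benjamini-Hochberg adjustment;
    transcription-factor target enrichment cross-validated by expression
    correlation against an empirical chance baseline; and survival meta-analysis
    combining per-cohort proportional-hazards score tests with Fisher's method.
    A synthetic-data module generates networks, paired expression studies,
    TF-target maps and survival cohorts with planted structure so that every
    stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    utils
Suggests:
    jsonlite,
    survival,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
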