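Package: mirprop
Title: Network Propagation and Paired Expression Screening for microRNA
    Target Pathway Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An in-silico pipeline for prioritizing disease pathways targeted
    by a microRNA, modelled on uterine leiomyoma versus patient-matched
    myometrium. Provides paired differential-expression screening
    (fold change, paired t-test, Benjamini-Hochberg FDR, complete-linkage
    clustering), exact hypergeometric and Fisher overlap testing between
    predicted target gene sets and curated disease gene sets, seed-based
    propagation over confidence-weighted gene interaction networks (naive
    Bayes neighbour evidence and random walk with restart) with AUC
    validation against held-out disease genes, and statistics for
    functional assay readouts (comparative-Ct relative quantification,
    wound closure, collagen gel contraction, exact small-sample tests).
    A synthetic-data module generates scale-free networks with planted
    disease modules, gene sets with controlled overlap, paired log-normal
    expression matrices with planted fold changes, and qPCR Ct tables, so
    every stage of the pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    Matrix,
    methods,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
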