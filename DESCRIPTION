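Package: dynetrank
Title: Disease-Gene Prioritization on Background-Temporal Multilayer Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds stage-wise dynamic protein-protein interaction networks
    from staged expression data using a k-sigma gene-activity model, couples
    them to a static background network in a multilayer graph, and ranks
    genes for disease association by a random walk with restart seeded from
    stage-wise differential-expression statistics. Includes control-set
    benchmark construction (artificial linked interval, randomized, whole
    genome), ranking metrics (top-k precision/recall, AUROC, AUPRC), and a
    synthetic-data generator with a planted, stage-progressive disease
    module on a scale-free interaction network.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    stats,
    utils
Suggests:
    limma,
    optparse,
    jsonlite,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
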