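Package: stressmod
Title: Stress-Tolerant Gene Co-Expression Modules for Myeloid Cell
    Transcriptomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Discovers gene co-expression modules that remain induced in
    monocytic myeloid-derived suppressor cells (M-MDSCs) under cellular
    stress, and evaluates them as cross-source MDSC signatures. Implements
    consensus weighted co-expression network construction on metacells
    (signed adjacency, topological overlap, static tree cut, module
    eigengenes and kME), dual-contrast classification of genes into
    stress-tolerant versus stress-sensitive quadrants, module
    down-selection, z-score signature scoring with logistic/ROC
    evaluation, pre-ranked gene set enrichment with a Monte-Carlo
    permutation null, expression-based somatic copy-number inference, a
    centroid label-transfer classifier, and a fully seeded synthetic
    single-cell and multi-source bulk data generator with planted ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    igraph,
    jsonlite,
    methods,
    stats,
    tools,
    utils,
    yaml
Suggests:
    fgsea,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
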