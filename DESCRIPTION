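Package: phylotempo
Title: Phylostratigraphy and Evolutionary Transcriptomics of Developmental
    Time Courses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Assigns gene ages (phylostrata) by Dollo parsimony over a rooted
    species tree and an orthogroup presence/absence matrix, filters and
    clusters replicated developmental time-course expression data by a
    consensus co-expression scheme that leaves non-conforming genes
    unassigned, computes transcriptome age index (TAI) profiles with a
    permutation-based reductive-hourglass test, summarizes expression
    variability and level by phylostratum, and performs Fisher-exact
    enrichment of phylostrata within co-expression clusters. Includes
    simulators for phyletic patterns with known gene ages and for time-course
    expression with planted clusters and a tunable hourglass signal, so every
    stage of the pipeline can be exercised against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    ape,
    mclust,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
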