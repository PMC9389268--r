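Package: triohet
Title: Inheritance Pattern Classification and Expression Heterosis for
    Parent-Hybrid Trio RNA-Seq
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of gene expression inheritance in a trio design: two
    inbred parents and their F1 hybrid profiled by replicated RNA-seq.
    Starting from a gene-level count matrix, the package computes FPKM and
    median-of-ratios size factors, performs pairwise negative-binomial
    differential expression between genotypes, classifies differentially
    expressed genes into twelve inheritance patterns (additive, dominant and
    over-dominant expression), computes mid-parent, high-parent and
    low-parent heterosis indices and per-gene expression heterosis, and runs
    hypergeometric term over-representation with Benjamini-Hochberg
    correction. A negative-binomial trio simulator with planted inheritance
    patterns provides ground-truth data for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2,
    optparse
biocViews: Transcriptomics, DifferentialExpression, GeneExpression,
    Sequencing, Normalization
Config/testthat/edition: 3
RoxygenNote: 7.3.3
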