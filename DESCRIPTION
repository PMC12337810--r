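Package: MethylScape
Title: DNA Methylation Landscapes, Group Relatedness Networks and Cell-Type
    Decomposition for Tumor Methylation Arrays
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for placing tumor entities in a DNA methylation landscape
    from Illumina EPIC-style beta-value matrices: sample quality control on
    detection p-values, top-variance CpG selection, t-SNE embedding,
    hierarchical and agglomerative consensus clustering with a
    consensus-degree group test, an internally implemented moderated-t
    differential methylation statistic with empirical-Bayes variance
    shrinkage, all-pairs DMP counting, a DMP-count-binned group relatedness
    network, TSS-based hyper/hypomethylation pathway direction calls with
    hypergeometric enrichment, and reference-based cell-type fraction
    decomposition. Includes a synthetic EPIC-like cohort generator with
    planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    matrixStats,
    Rtsne,
    igraph,
    ape,
    pracma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    limma,
    optparse
Config/testthat/edition: 3
biocViews: DNAMethylation, MethylationArray, DifferentialMethylation,
    Clustering, Network, Epigenetics
RoxygenNote: 7.3.3
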