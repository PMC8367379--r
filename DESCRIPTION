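Package: asedyn
Title: Allele-Specific Expression Dynamics and CRE-seq Reporter Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for detecting cis-acting variation in gene expression
    dynamics from allele-resolved RNA-seq timecourses. Implements
    median-of-ratios normalization, weighted tests for allele-specific
    expression (ASE) levels and a weighted Durbin-Watson test for ASE
    dynamics with permutation-based null calibration, k-means clustering
    of expression and allele-frequency trajectories, logistic regression
    of ASE status on variant burden, design of barcoded cis-regulatory
    element (CRE-seq) reporter libraries with single-variant swaps and
    inter-specific chimeras, analysis of CRE-seq RNA/DNA barcode counts
    (expression, allele, variant and chimera tests), and variant
    annotation with conservation scores and position-weight-matrix
    binding-change scores. Includes seeded generators of synthetic
    allele-count timecourses, toy genomes and CRE-seq count tables for
    calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    lmtest,
    DESeq2,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
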