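Package: equimir
Title: Equine miRNome Discovery and Expression Analysis from Small RNA-Seq Read Stacks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for microRNA discovery and expression analysis in horse
    (Equus caballus) small RNA sequencing data, starting from aligned,
    collapsed read stacks. Implements biogenesis-criteria hairpin candidate
    excision and evaluation with a self-contained RNA secondary structure
    folder, log-odds candidate scoring with permutation-based signal-to-noise
    calibration, cross-sample catalog consolidation with known-miRNA
    annotation and genomic clustering, cpm/TMM expression quantification
    with tissue- and breed-specificity calling, and two-group negative
    binomial exact-test differential expression with Benjamini-Hochberg
    correction. A seeded synthetic-data generator (toy genomes, planted
    hairpin loci, biogenesis-shaped read stacks, negative binomial count
    matrices with planted effects) makes every stage testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    BiocGenerics,
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    SummarizedExperiment
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    jsonlite,
    rtracklayer
Config/testthat/edition: 3
biocViews: Sequencing, SmallRNA, GeneExpression, DifferentialExpression,
    Normalization
RoxygenNote: 7.3.3
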