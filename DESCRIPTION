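Package: cssmisreg
Title: Transcriptional Misregulation Analysis for Chromosome Substitution Strains
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for transcriptome comparisons between a host
    inbred strain, a donor (sub)species strain, and chromosome substitution
    strains (CSS) carrying donor-derived chromosomes or sub-chromosomal
    regions. Implements microarray probe-set polymorphism scoring and
    pre-analysis filtering, empirical-Bayes moderated t-tests with
    Benjamini-Hochberg FDR and fold-change calling, chromosome-stratified
    Ansari-Bradley dispersion tests on centred fold changes, classification
    of misexpressed transcripts into cis-regulatory versus incompatibility
    types by convergence toward the donor strain, PCA-based restored /
    non-restored typing of F1 individuals, and backcross QTL mapping by
    single-marker regression and Haley-Knott interval mapping. A synthetic
    data generator with known ground truth emulates the statistical
    structure of such studies so the full pipeline is testable without
    array data.
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
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    limma,
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'synthetic.R'
    'probe-filtering.R'
    'diff-expression.R'
    'dispersion.R'
    'classification.R'
    'sample-structure.R'
    'qtl.R'
    'io.R'
    'pipeline.R'
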