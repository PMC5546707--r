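Package: epifunc
Title: Tissue-Specific Functional Annotation of the Genome from Integrated Epigenomic Tracks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrates binary epigenomic and transcriptomic annotation tracks
    into per-nucleotide tissue-specific functionality scores with a two-class
    Bernoulli mixture model fitted by expectation-maximization, and provides the
    downstream machinery built on such scores: track algebra (binarization,
    smoothing, union/mean combination, quantile dichotomization), a tissue
    specificity index for expression matrices, annotation-stratified LD-score
    regression with jackknife heritability enrichment, a window-based
    cross-trait pleiotropy test (hypergeometric and permutation), Bayesian
    reprioritization of GWAS SNPs from p-values and annotation scores, and
    sample-size-based meta-analysis z-score algebra. Includes synthetic-data
    generators with machine-readable planted truth for every component.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
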