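Package: famMeth
Title: Family-Based Heritability and meQTL Classification of DNA Methylation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Variance-component analysis of DNA methylation in extended
    pedigrees. Fits a kinship linear mixed model per CpG by profiled REML to
    estimate broad-sense heritability, classifies highly heritable CpGs into
    cis-meQTL, trans-meQTL and genotype-independent categories by an
    expanding-window SNP association scan, estimates weighted correlations for
    typed relative pairs, screens genotype-independent CpGs for private family
    effects in the beta-score extremes, applies Illumina 450k-style quality
    control (detection-p masking, sample/probe/SNP filters, Infinium I/II
    chemistry correction, methylation principal components), and runs
    categorical annotation enrichment tests. Includes a pedigree and
    methylation simulator (gene dropping, kinship-structured genetic variance,
    planted meQTLs, shared-household effects, array artifacts) so every stage
    is testable with known ground truth.
License: MIT
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
    data.table,
    jsonlite,
    yaml,
    vcfR,
    rtracklayer
Suggests: testthat (>= 3.0.0), optparse, withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
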