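Package: bslink
Title: Linked Bisulfite Read-Pair Analysis of GpC Methyltransferase
    Footprints
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Downstream analysis of bisulfite-converted Hi-C read pairs
    carrying exogenous GpC methyltransferase footprints (chromatin
    accessibility) and endogenous CpG methylation. Builds strand-aware
    cytosine-context indexes (GCH/HCG/WCG/CCG and non-CpG contexts) of a
    reference genome, extracts per-read methylation calls with mapping,
    base-quality, duplicate and bisulfite-conversion filters, quantifies
    single-molecule footprint concordance between chromatin loop anchors
    against a mean-preserving shuffle null (Pearson, Phi and tetrachoric
    correlation with a Fisher z comparison), calls long-range
    allele-specific footprints at heterozygous SNPs with Fisher exact
    tests and Benjamini-Hochberg correction, and post-filters bisulfite
    genotype calls. A seeded simulator generates references, loop
    anchors, aligned read pairs with planted footprint correlation and
    allelic effects, and crafted variant tables for testing every stage
    at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    Rsamtools,
    GenomicAlignments,
    mvtnorm,
    jsonlite
Suggests:
    SummarizedExperiment,
    testthat (>= 3.0.0),
    withr,
    VariantAnnotation,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
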