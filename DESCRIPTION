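Package: TNBCconcord
Title: TNBC Molecular Subtyping Concordance Between Fresh-Frozen and FFPE RNA-seq
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Nearest-centroid molecular subtyping of triple-negative breast
    cancer (TNBC) expression profiles with prediction strength and confidence
    scoring, and tools to quantify how tissue preparation affects subtype
    calls. Implements paired fresh-frozen (FF) versus formalin-fixed
    paraffin-embedded (FFPE) concordance statistics with Clopper-Pearson
    exact binomial intervals, a negative-binomial Wald test for
    preparation-differential transcripts with median-of-ratios
    normalization, transcript-class and length bias accounting, exon-level
    3' positional bias statistics, hypergeometric gene-set
    overrepresentation, centroid gene-set reduction, and a seeded synthetic
    paired FF/FFPE cohort generator with known ground truth so that every
    pipeline stage is verifiable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2,
    rtracklayer,
    GenomicRanges,
    BiocGenerics
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Transcriptomics, RNASeq, Classification, GeneExpression,
    DifferentialExpression
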