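Package: chromdiff
Title: Desk-Scale ChIP-Seq Co-Occupancy, State Enrichment and Consensus
    Differential Binding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A compact, fully testable pipeline for the downstream
    computations of a native ChIP-seq study of chromatin-factor binding:
    fragment-extension coverage tracks with 1x depth normalization,
    meta-gene profile matrices with k-means cluster extraction and
    gene-body versus downstream signal comparison, observed/expected
    chromatin-state overlap enrichment, dual-criterion peak co-occupancy
    (interval overlap or twofold normalized read-count enrichment), a
    two-algorithm consensus differential-binding caller (windowed
    negative-binomial exact test plus peak-based negative-binomial Wald
    test), histone-PTM isoform quantification with isobaric MS2-fragment
    deconvolution, and qPCR percent-input and 2^-ddCt analysis. A
    synthetic-data generator with planted ground truth makes every stage
    verifiable without access to deposited sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    BiocGenerics,
    data.table,
    MASS,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2,
    ggplot2
Config/testthat/edition: 3
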