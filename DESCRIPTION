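Package: cmuscan
Title: Correlated Methylation Unit Detection by Image Clustering of
    CpG Correlation Matrices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects correlated methylation units (CMUs) from Illumina
    450K/EPIC-style beta-value matrices by treating per-window CpG
    correlation matrices as images: smoothing with an unequal-weight box
    filter, thresholding, and gradient-based edge detection delimit runs
    of co-methylated probes (contiguous CMUs), which are then linked into
    non-contiguous CMUs by strong signed inter-block correlation.
    Downstream statistics include an asymmetric (Tversky alpha=1, beta=0)
    similarity between CMU sets, tissue-independent CMU calling by
    basepair coverage stacking, probe- and region-based regulatory
    feature enrichment with matched random backgrounds, chromatin-context
    overlap summaries including an A/B-compartment pair score, and
    case-control differential-correlation testing combining a
    Steiger-type chi-square matrix comparison with a shifted Wilcoxon
    rank-sum test. A seeded synthetic-data generator with planted
    correlation blocks supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    Matrix,
    jsonlite,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
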