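Package: prstress
Title: Pathogenesis-Related Gene Stress-Response Analysis for Time-Course
    Transcriptomes
Version: 0.1.0
Authors@R:
    person("PR", "Stress Team", email = "prstress@example.org",
           role = c("aut", "cre"))
Description: A pipeline for genome-wide analysis of pathogenesis-related
    (PR) defense-gene families in time-course RNA-seq experiments.
    Implements differential-expression calling on negative-binomial counts
    with field-standard thresholds (|log2FC| > 1, FDR <= 5 percent, low-count
    filtering), classification of genes into temporal (early/late/sustained)
    and hormone (salicylic-acid/jasmonic-acid) expression programs,
    cross-genotype trend clustering, phylogeny-based clade nomenclature and
    species-specific family-expansion detection, tandem physical-cluster
    detection from gene coordinates, cross-stress log2 fold-change
    consolidation with outlier-robust Pearson correlation, and comparative-Ct
    qPCR validation. Ships a negative-binomial count simulator with planted
    ground truth so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    phangorn,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
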