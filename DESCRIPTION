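Package: chipms
Title: Location Prediction for Chromatin-Bound Proteins from
    Histone-Modification ChIP-MS
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analyses chromatin proteomics (ChIP-MS) experiments in which
    proteins co-precipitating with histone modifications (H3K4me3, H3K4me1,
    H3K27ac, H3K9me3) are identified by mass spectrometry.  Computes emPAI
    semi-quantitative protein abundances, applies Mascot-score and
    fold-enrichment inclusion filters against a GFP control, and predicts for
    each factor whether it binds promoters, enhancers or heterochromatin,
    together with an H3K27ac activity ratio.  Validates predictions against
    ChIP-seq data: genome-wide binned Spearman correlation of factor binding
    with histone marks, promoter/enhancer region assignment with
    H3K27ac-ranked occupancy heatmaps, peak summit overlap analysis, and
    bound/target gene calling with expression comparisons.  Includes a
    seeded synthetic-data generator with planted ground truth so the whole
    pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
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
    DESeq2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
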