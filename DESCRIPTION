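Package: mitomir
Title: Mitochondrial miRNA Enrichment, Targeting and Structural Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to identify and characterize mitochondrially enriched
    microRNAs (mitomiRs) from dual-channel (Hy5/Hy3) microarray data:
    background filtering and spike-in calibrator normalization, fold-change
    classification of mitochondrial versus cytosolic enrichment, seed-site
    scanning of a circular mitochondrial genome with a Poisson random-match
    statistic, exact mapping of mature miRNAs to mtDNA, RNA secondary-structure
    thermodynamic features (MFE, AMFE, MFEI) from a reduced nearest-neighbor
    folding engine, cross-species conservation scoring, pixel-wise
    co-localization statistics (Pearson coefficient and Van Steensel
    cross-correlation), and a synthetic-data module that generates every input
    with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    withr,
    png,
    tiff,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    rtracklayer,
    pheatmap
Config/testthat/edition: 3
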