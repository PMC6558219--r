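Package: sicobind
Title: Signal Integration and STAT1/NF-kB Co-Binding Analysis for RNA-seq and ChIP-seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Integrative analysis of interferon (IFN) plus lipopolysaccharide (LPS)
    transcriptional synergy and STAT1/p65 genomic co-binding. Provides median-of-ratios
    normalization, fold-change and signal-integration (super-additivity) calling on
    replicate count matrices; two position-weight-matrix scanning dialects (genome-wide
    log-odds with per-class score thresholds, and min-max matrix-similarity promoter
    scanning); peak-to-gene annotation with a nearest-TSS distance filter and a
    seven-way genomic-location classification; single versus co-binding mode
    classification over GAS, ISRE and NF-kB motif classes; summit-distance histograms;
    RPKM occupancy clustering; a seeded multi-omic simulator with planted ground truth;
    and a configuration-driven pipeline with machine-readable reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    Biostrings,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2,
    fgsea,
    mclust
Config/testthat/edition: 3
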