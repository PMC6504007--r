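Package: embryodyn
Title: Transcriptome Dynamics of Cloned and In Vivo Fertilized
    Pre-Implantation Embryos
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Analysis pipeline for staging the pre-implantation embryo
    transcriptome from bulk RNA-seq count matrices, motivated by porcine
    somatic-cell nuclear transfer (SCNT) studies. Provides FPKM
    quantification with expressed-gene calling, median-of-ratios and
    trimmed-mean (TMM) normalization, exact-test differential expression
    for unreplicated and negative-binomial replicated designs with
    Benjamini-Hochberg adjustment, successive-stage DEG profiling,
    stage-specific and first-expressed (embryonic genome activation) gene
    classification, inner-cell-mass marker identification from bisected
    blastocysts, gene-panel trajectory extraction, sample-level QC
    (hierarchical clustering, PCA, pairwise R-squared), and a seeded
    synthetic embryo-transcriptome simulator with planted ground truth for
    recovery testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    GenomicRanges,
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
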