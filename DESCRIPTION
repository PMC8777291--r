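Package: circpept
Title: Discovery of Circular RNA-Encoded Proteins from Cross-Omics Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for discovering novel proteins encoded
    by circular RNAs (circRNAs) in a two-group disease-model design. Provides a
    self-contained simulator that plants junction-spanning open reading frames
    (ORFs) and a matched proteomics layer with known ground truth; a circRNA
    catalog module that classifies genomic origin and extracts mature circular
    sequences; TPM-based differential expression with fold-change and p-value
    thresholds, Benjamini-Hochberg FDR, and an exact Mann-Whitney U test;
    junction-spanning ORF prediction on circular templates with rolling-circle
    bookkeeping; in-silico tryptic digestion and unique-region peptide evidence
    scoring; and cross-omics integration into a tiered candidate table.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    GenomicRanges,
    GenomeInfoDb,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
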