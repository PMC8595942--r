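Package: piezoregulon
Title: Pressure-Responsive Gene Regulation Analysis for Archaeal Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for studying transcriptional regulation under
    high hydrostatic pressure in Thermococcales. Extracts strand-aware promoter
    regions from a genome and its annotation, screens them for gapped degenerate
    transcription-factor binding motifs (SurR-style GTTn3AAC / GTTn3AACn5GTT
    patterns or any user-supplied pattern), normalizes RNA-seq count matrices
    (TPM and median-of-ratios size factors), performs negative-binomial Wald
    differential-expression tests with Benjamini-Hochberg correction, and
    summarizes regulon/DEG overlaps, per-cluster overexpression tables, Venn
    counts and EASE enrichment statistics. Includes a fully seeded synthetic-data
    generator (genomes with planted motifs, NB counts with planted fold changes)
    so every stage is testable without external downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    DESeq2,
    edgeR,
    mclust,
    optparse,
    stringi,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
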