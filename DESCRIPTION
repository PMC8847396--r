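Package: clonoscope
Title: Paired-Chain Single-Cell TCR Repertoire Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis of paired alpha/beta T cell receptor repertoires from
    single-cell V(D)J sequencing. Reads 10x Genomics contig annotation and
    AIRR Rearrangement tables, assembles quality-filtered cells carrying
    exactly one TRA and one TRB chain, defines clones by paired CDR3
    nucleotide identity, and quantifies clonal expansion, Shannon
    entropy and evenness, cross-sample clonal overlap, CDR3 amino-acid
    edit-distance similarity networks, V-gene germline usage and pairing,
    and the association between clonal expansion and per-cell
    transcriptional cluster labels. Includes a seeded synthetic repertoire
    generator with ground truth for end-to-end validation, and a pipeline
    runner that orchestrates all stages from a single configuration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
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
    utils
Suggests:
    Biostrings,
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
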