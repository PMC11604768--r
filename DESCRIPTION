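Package: trempra
Title: Design and Analysis of Barcoded Synthetic-Promoter Reporter Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A desk-scale workflow for massively parallel reporter assays
    (MPRA) built on transcription-response-element (TRE) synthetic promoters.
    Converts position-weight-matrix seed sequences into a deduplicated
    binding-motif catalog, designs 160-nt TRE-unit oligos with four
    helically phased motif copies crossed with three minimal promoters,
    builds barcode-to-promoter dictionaries from paired dictionary reads,
    collapses sample barcodes by greedy sphere clustering at edit distance
    one, estimates per-promoter transcription rates as aggregate RNA/DNA
    reads-per-million ratios, and tests condition-dependent promoter
    activity with a two-stage negative-binomial likelihood-ratio model.
    Includes a synthetic-data generator emulating the statistical structure
    of a barcoded plasmid screen so every stage is testable without
    external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
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
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
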