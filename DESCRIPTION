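Package: chemotif
Title: Chemical-Group Characterization of Protein Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Alignment-free characterization of protein sequences through a
    reduced amino-acid alphabet of eight side-chain chemistry groups (acidic,
    basic, aromatic, aliphatic, cyclic, sulfur-containing, hydroxyl-containing,
    acidic amide). Provides digit-string encoding of sequences, 8x8
    chemical-group transition matrices with per-group ordered-pair summaries,
    discovery of chemically conserved patterns shared by every sequence in a
    set (with or without repetition of groups, including maximal-length
    search), sliding-window block-similarity scanning, discriminating-group
    analysis of sequence-set bipartitions, a planted-motif synthetic sequence
    generator, FASTA input/output, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    stringr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    readr,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
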