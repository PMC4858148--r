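Package: circamir
Title: Circulating miRNA Biomarker Discovery from Small RNA-Seq and RT-qPCR
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tidyverse-style pipeline for discovering circulating microRNA
    biomarkers of pubertal stage from small RNA sequencing of serum and plasma,
    with a ground-truth simulator for end-to-end validation. Covers read
    cleaning and tag collapsing, conserved miRNA annotation by exact catalog
    match, novel miRNA precursor prediction with a nested-pairing folder and an
    eleven-criterion hairpin filter, reads-per-million normalization with
    Fisher's exact and chi-square differential expression between stages,
    candidate screening, and RT-qPCR relative quantification (2^-ddCq) with a
    temporal panel-classification rule for puberty-onset biomarkers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    S4Vectors,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
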