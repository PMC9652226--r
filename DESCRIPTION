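Package: stallmpra
Title: Massively Parallel Reporter Analysis of Dicodon Repeats and
    Nascent-Peptide Stalling Motifs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Design and analysis toolkit for pooled reporter assays that
    measure the effect of coding-sequence dipeptide motifs on mRNA levels.
    Generates dicodon and dipeptide-repeat reporter libraries with random
    VNN barcodes, simulates linkage and barcode-count sequencing data under
    an explicit generative model, builds and filters barcode-to-insert
    maps, quantifies per-insert mRNA levels with bootstrap uncertainty,
    fits physicochemical (isoelectric point, bulkiness, beta-strand
    propensity) models of nascent-peptide effects, scans proteomes for
    destabilizing charged-bulky dipeptide motifs, and estimates ribosome
    transit times from continuous luminescence traces.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    rlang,
    methods,
    jsonlite,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
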