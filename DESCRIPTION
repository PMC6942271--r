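Package: homeologr
Title: Subgenome Reconstruction and Homeolog Dominance Analysis After
    Whole-Genome Duplication
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs the two post-duplication subgenomes of a paleo-
    tetraploid genome (e.g. maize) from syntenic anchor blocks against an
    unduplicated outgroup (e.g. sorghum), extracts retained homeolog pairs,
    classifies tissue-specific expression- and protein-abundance-level
    dominance between homeologs, computes the expression/abundance
    correlation structure across tissues, and compares Gene Ontology,
    reaction/pathway and isoform annotations between subgenomes. Ships a
    seeded generator of complete synthetic fractionation studies (anchor
    blocks with Ks, quantification matrices with planted dominance
    categories, annotations with planted asymmetries) so the whole pipeline
    runs and is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
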