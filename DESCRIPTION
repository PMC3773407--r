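Package: cgcphy
Title: Whole-Genome Prokaryotic Phylogenies from Conserved Gene Cluster Distances
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Infers prokaryotic phylogenies from whole-genome annotation data.
    Orthologous genes are assigned between genome pairs by maximising sequence
    similarity under COG functional-category filtering and operon-parsimony
    penalties; putative horizontally transferred genes are eliminated both as
    highly conserved genes (ratio-of-orthologous-genes calibration with a
    three-sigma rule) and as genes on fragments with abnormal 4-mer genome
    barcodes; pairwise distances are the negative log10 of the number of
    orthologous genes lying in conserved (collinear or inverted) gene clusters;
    trees are built by neighbor-joining and scored against a rank-coded
    reference taxonomy by quartet topology agreement. A synthetic-clade
    generator evolves annotated genomes along a known tree, with planted
    horizontal transfer, so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
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
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
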