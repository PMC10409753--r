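Package: cellphylo
Title: Phylogenetic Inference from Single-Cell RNA-Seq Genotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs the evolutionary relationships among single cells
    profiled by single-cell RNA sequencing. Converts per-site reference and
    alternate allele read counts into genotype probabilities with a
    beta-binomial model, smooths the probabilities across the k nearest
    neighbours of each cell to overcome dropout, filters variant sites by
    coverage and informativeness, and exports phylogeny-ready alignments.
    Includes a neighbour-joining fallback tree builder, phylogenetic-signal
    statistics (Pagel's lambda, Blomberg's K), standardized-effect-size mean
    pairwise distance, the adjusted Rand index, and a clade-structured
    synthetic-data simulator with robustness-sweep harnesses.
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
    Matrix,
    mclust,
    phangorn,
    picante,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr
Suggests:
    phytools,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
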