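Package: magnetochrome
Title: Harvest and Evolutionary Analysis of Magnetochrome Domains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the magnetochrome (MCR) domain, the short
    (19-28 residue) mono-heme c-type cytochrome domain found in tandem in
    the magnetosome proteins MamE, MamP, MamT and MamX of magnetotactic
    bacteria. The package compiles and scans a PROSITE-dialect protein
    pattern to harvest MCR domains from protein FASTA files, delineates
    domain boundaries from the CXXCH heme-attachment anchor, aligns the
    harvested domains with a deterministic progressive aligner, builds
    neighbor-joining trees from JTT maximum-likelihood distances, and
    turns the qualitative question of whether the tandem arose by
    duplication-before-divergence or divergence-before-duplication into a
    permutation-tested parsimony statistic. A sequence-evolution simulator
    generates ground-truth datasets under either duplication-order model
    so that every stage of the pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
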