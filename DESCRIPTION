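Package: mirloci
Title: Discovery and Expression Profiling of Plant miRNA Loci from Small RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for discovering plant microRNA loci
    from collapsed small-RNA sequencing reads: greedy count-ordered read
    clustering, pairing of clusters into pre-miRNA candidates, hairpin
    validation against a minimum-free-energy threshold with a built-in
    nearest-neighbour folding engine, homology expansion of mature
    sequences, two-condition expression profiling (reads-per-million,
    fold-change, 3p/5p arm ratio, antisense small RNAs), canonical-anchored
    isomiR classification including non-templated 3' additions, and
    miRNA target validation from degradome 5'-end tags with canonical
    cleavage calling at miRNA positions 10-11. Ships a deterministic
    synthetic-data generator that emulates two-condition small-RNA
    libraries with planted hairpin loci for end-to-end benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    rtracklayer,
    jsonlite,
    withr
Config/testthat/edition: 3
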