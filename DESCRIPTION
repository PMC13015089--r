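Package: epsmatch
Title: Filter-Accelerated Search for Error-Bounded Local Alignments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Finds all local alignments between two DNA sequence sets that
    reach a minimum length and stay under a maximum edit-distance rate
    (epsilon-matches), using a two-level k-mer prefilter: an Interleaved
    Bloom Filter over overlapping reference segments followed by a lossless
    diagonal q-gram filter, feeding banded Waterman-Eggert local alignment.
    Includes a probabilistic model that deduces the k-mer weight and shared
    count threshold by minimising the sum of filter false negative and false
    positive rates, canonical gapped (spaced) seed support, repeat-aware bin
    selection, a seeded benchmark generator with implanted alignments, and
    an evaluator for match recall.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
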