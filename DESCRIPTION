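Package: dbhash
Title: Succinct Hash Indexing and Randomized k-Mismatch Short-Read Alignment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the dB-hash data structure: a Hamming-aware de Bruijn
    hash function maps a DNA reference to a fingerprint string, and a
    Burrows-Wheeler index with wavelet-tree rank support over that fingerprint
    string simulates hash lookups in succinct space. On top of the index, a
    randomized k-mismatch search enumerates a squeezed Hamming ball in
    fingerprint space, verifies candidates against a 3-bit packed copy of the
    plain text, and optionally restricts the search using Phred base
    qualities. Includes FASTA/FASTQ input, SAM output, a synthetic read
    simulator with position truth, and an alignment evaluator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    tibble,
    dplyr,
    rlang,
    generics,
    ggplot2,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
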