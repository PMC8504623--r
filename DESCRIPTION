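Package: crisphage
Title: Phage-Host Prediction from CRISPR Spacers by Protein-Level Matching
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts phage-host relationships by matching CRISPR spacers
    from prokaryotic genomes against phage genomes at the protein level.
    Spacers and phage genomes are six-frame translated into putative coding
    fragments, compared with a spaced k-mer prefilter followed by
    Smith-Waterman local alignment under a short-distance substitution
    matrix, and re-aligned at the nucleotide level to flag near-perfect
    protospacers. Per-spacer best-hit P-values are combined into a per-pair
    score with a truncated-product method, and matches are filtered by an
    empirical false discovery rate estimated from a reversed-sequence null
    database. Retained protospacers are scanned for flanking PAM motifs,
    and weighted lowest-common-ancestor taxonomy reports can be produced.
    Includes parsers for PILER-CR, CRT, MinCED and CRISPRDetect output and
    a synthetic benchmark generator with planted protospacers.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    jsonlite,
    methods,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
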