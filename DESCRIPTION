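Package: flowalign
Title: Homopolymer-Aware Frame-Shift Alignment of Pyrosequencing Reads to
    Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Local alignment of nucleotide reads against protein sequences
    with frame-shift-capable dynamic programming, designed for 454/Ion
    Torrent style pyrosequencing data where homopolymer length miscalls
    dominate the error profile.  Extends the Smith-Waterman-Gotoh algorithm
    so that one amino acid may be matched by 1, 2, 4 or 5 query nucleotides,
    with position-specific frame-shift penalties derived from flowgram peak
    values (SFF input) or called homopolymer lengths (FASTA input).
    Includes an SFF v1.00 reader and fixture writer, a flow-space read
    simulator with ground-truth homopolymer over/undercall bookkeeping, and
    a Matthews-correlation benchmark of indel recovery across alignment
    models.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    methods,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
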