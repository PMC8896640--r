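Package: seqcodec
Title: Block Compression Codecs for Sequencing Data Streams
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Entropy coders and reversible data transforms for the byte
    streams found in columnar genomic file formats: a static-frequency rANS
    coder with 16-bit renormalization and 4- or 32-way state interleaving,
    bit-packing, run-length and byte de-interleaving transforms, an adaptive
    byte-wise range coder, a context-model quality-score codec in the
    FQZComp family, and a structure-aware read-name tokenizer with delta
    encoding. Includes seeded generators for NovaSeq-, HiSeq- and
    PacBio-like quality strings and Illumina-style read names, plus a
    benchmark harness with round-trip verification.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
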