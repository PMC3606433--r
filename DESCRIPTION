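Package: fqzlite
Title: Stream-Split Compression of FASTQ and SAM Sequencing Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Lossless and lossy compression of high-throughput sequencing data
    by splitting FASTQ and SAM files into identifier, base-call, quality and
    alignment streams and coding each stream with adaptive context models under
    a byte-wise arithmetic (range) coder. Implements tokenised identifier
    delta coding, multi-level quality contexts, order-k base models with
    optional reverse-complement training, self-synchronising 3/4-base packing
    with a logistic context-mixing model stack, hash-indexed reference
    alignment coding, per-reference-position base models for position-sorted
    SAM, and a reference-difference model for name-sorted SAM. Includes a
    synthetic Illumina-style read simulator so every codec is testable without
    external data, a single-file container format with per-stream checksums,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
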