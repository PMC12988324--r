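Package: traelr
Title: Replication Profiling from Multiplexed TrAEL-seq Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for processing multiplexed TrAEL-seq libraries, which capture
    free 3' single-stranded DNA ends (predominantly replication-fork leading
    strands) genome-wide. Covers inline-barcode demultiplexing with 8-nt UMI
    extraction and poly-T trimming, copy-number-aware UMI deduplication of
    aligned reads, single-base break mapping, replication fork directionality
    (RFD) track computation, hidden Markov model segmentation of initiation and
    termination zones, read-density profiling as a function of distance from
    initiation zones (with stratification, AUC comparison and gene metaplots),
    and a replication-fork simulator that generates truth-labelled reads for
    end-to-end validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    Rsamtools,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    optparse,
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
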