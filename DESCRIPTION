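Package: delnet
Title: Deletion Calling from Long-Read Alignments with a Time-Distributed
    CNN-BLSTM Window Classifier
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects deletions (>= 50 bp) in coordinate-sorted long-read
    alignments. Reference windows are summarised as binary per-read deletion
    bitmaps built from CIGAR D operations, sequences of windows are scored by
    a time-distributed convolutional encoder with squeeze-and-excitation
    blocks feeding a bidirectional LSTM and a sigmoid classification head
    trained with a class-asymmetric logarithmic loss, and positive windows
    are refined into precise breakpoint calls by single-linkage clustering of
    per-read deletion signatures. Includes a long-read alignment simulator
    with implanted deletions so the full pipeline can be trained and
    evaluated without external data, plus precision/recall/F1 and AUC
    benchmarking utilities and VCF output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    Rcpp,
    Rsamtools,
    S4Vectors,
    SummarizedExperiment,
    VariantAnnotation,
    jsonlite,
    pROC,
    rtracklayer,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
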