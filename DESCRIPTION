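Package: nascentHMM
Title: De Novo Transcription Unit Discovery from Nascent Transcription
    Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Calls transcription units de novo from strand-specific
    nascent-transcription sequencing data (GRO-seq and related run-on
    assays) using a two-state hidden Markov model with gamma-distributed
    emissions over windowed read counts.  Provides constrained Baum-Welch
    training with two held-out tuning parameters, Viterbi decoding to
    stranded transcription-unit intervals, grid-search model selection
    against reference annotations, consensus-annotation construction from
    multi-source gene models, evaluation metrics (merged/dissociated
    annotation errors and transcription-unit accuracy), annotation-guided
    boundary repair, classification of called units into ten functional
    transcript categories, bidirectional enhancer-transcript pair
    detection with cell-type-specificity scoring, metagene profiling, and
    a seeded gamma-Poisson read simulator with planted gene and enhancer
    layouts for offline benchmarking.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    graphics,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
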