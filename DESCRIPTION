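Package: slamwave
Title: Metabolic RNA Labeling Time Courses and Transcription-Factor Target Waves
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for inducible transcription-factor activation
    time courses read out by thiol-linked alkylation metabolic RNA sequencing
    (SLAM-seq). Provides a synthetic-study generator (reference, counting
    windows, aligned labeled reads with T>C conversion chemistry, occupancy
    peaks, ground truth), conversion-aware quantification with variant
    masking and labeled-read calling, empirical-Bayes moderated linear-model
    differential-transcription testing across the time course, occupancy
    peak-to-gene annotation, and integration of timing with occupancy to
    classify genes into immediate-early, delayed and secondary target waves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    Rsamtools,
    jsonlite,
    data.table
Suggests:
    testthat (>= 3.0.0),
    withr,
    limma
Config/testthat/edition: 3
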