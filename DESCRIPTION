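Package: promreg
Title: Promoter-Window Transcription-Factor Binding Regression of TSS Activity
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies how transcription-factor binding in defined promoter
    windows explains CAGE-derived transcription start site (TSS) activity.
    Implements consensus meta-processing of multi-caller ChIP-seq peak sets
    with quality-gated orphan removal, construction of promoter-window
    feature matrices (per-window binding-abundance ratios plus binary
    per-TF presence features), log-transformed expression (LTE) modelling
    by greedy forward least-squares feature selection with correlation
    traces and cross-validation, profile-commonality features (mean and
    predicted-mean profiles), sum-transformation of closely spaced TSSs,
    and location-dependent activator/repressor classification of TFs.
    Includes a fully seeded synthetic-data generator with known ground
    truth so the whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    optparse,
    IRanges,
    GenomicRanges,
    S4Vectors
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
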