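Package: songsift
Title: Time-Series Phenotyping and Context Classification of Birdsong Motifs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for expansive time-series phenotyping of zebra-finch song
    motifs and for linking acoustic classification to operant behavior. The
    package synthesizes courtship and non-courtship motif waveforms with
    controllable context effects, extracts a compact bank of named
    time-series features (time-irreversibility statistics, power-spectral
    summaries, symbolic dynamics, permutation entropy, autoregressive model
    fits, stationarity and forecasting measures, and an approximate
    SAP-style spectral baseline), normalizes feature matrices with a robust
    sigmoidal transform, classifies motifs by social context with bagged
    decision trees (cross-validation, importance-based feature selection,
    random-subset benchmarks, signed confidence scores), and quantifies
    learning and generalization in two-alternative forced-choice operant
    sessions via a sigmoid-plus-run-length criterion.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    signal,
    ranger,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
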