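Package: mieeg3d
Title: Compact 3D Convolutional Networks and Measurement-Condition
    Optimization for Motor-Imagery EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for decoding motor-imagery EEG under tight model-size
    budgets: a compact 3D convolutional network that consumes scalp-grid
    tensors, a reference EEGNet builder, exact parameter and
    multiply-accumulate (MACC) accounting with an instrumented-forward
    oracle, a staged electrode-elimination search, sample-window and
    subsampling sweeps with an accuracy-maintenance predicate, Pareto-front
    analysis of model size versus accuracy, ERD/ERS topography, and a
    seeded synthetic motor-imagery EEG simulator (1/f background plus
    lateralized mu/beta event-related desynchronization) so the whole
    pipeline runs without external recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    signal,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
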