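Package: imimr
Title: Interactive Mutual Information Modeling for Multimodal Bio-Signal Fusion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Weights heterogeneous physiological features (EEG band power,
    event-related potentials, heart-rate variability) by solving a
    box-constrained concave quadratic program over mutual-information
    dependency and pairwise interaction-information redundancy terms
    (interactive mutual information modeling, IMIM). Provides feature-level
    (IMIM-F) and classifier-level (IMIM-C) fusion with leave-one-subject-out
    cross-validation, EEG/ECG feature extraction from epoched signals and
    R-R interval series, and seeded synthetic generators emulating a
    three-level n-back mental-workload study.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    FNN,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    quadprog,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
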