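Package: gfconn
Title: Single-Trial Gaussian-Kernel Functional Connectivity for Motor-Related EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Feature extraction and decoding for motor-related EEG based on
    single-trial Gaussian-kernel functional connectivity. Implements a
    Butterworth filter-bank and sliding-window decomposition, pairwise
    channel connectivity measures (Gaussian kernel, Pearson cross-correlation,
    phase-locking value), CSP-style spatial projection, sparse elastic-net
    relevance selection over time-frequency connectivity features,
    stratified cross-validated classification, and a subject-clustering and
    topographic interpretation layer. Includes a synthetic coupled-oscillator
    EEG generator with planted class-dependent coupling so the whole pipeline
    is testable without external recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    MASS,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
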