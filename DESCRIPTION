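Package: eegicc
Title: Test-Retest Reliability of Phase-Lag EEG Connectivity Across Epoch Schemes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for studying the test-retest
    reliability of phase-lag-based EEG functional connectivity in data-limited
    (e.g. infant) recordings. Generates two-session multichannel recordings with
    known subject-level phase coupling, estimates the phase lag index (PLI) and
    debiased weighted phase lag index (dbWPLI) from Hanning-tapered Fourier
    coefficients, derives whole-brain connectivity and surrogate-normalised
    weighted graph metrics (clustering coefficient, characteristic path length,
    small-worldness index), and quantifies between-session reliability with the
    two-way fixed-model consistency intra-class correlation ICC(3,1) across
    epoch-segmentation designs trading off epoch number against epoch length.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    tools,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
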