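Package: aperiodic
Title: Aperiodic EEG Spectral Parameterization and Electrode-Cluster Inference
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating the aperiodic (1/f) component of EEG power
    spectra and testing condition effects on the aperiodic exponent. Implements
    Welch power spectral density estimation, decomposition of spectra into an
    aperiodic component plus Gaussian oscillatory peaks (spectral
    parameterization), electrode-space cluster-based permutation tests with
    max-statistic family-wise error control, and fully within-subject factorial
    ANOVA on exponent tables. Includes a synthetic-data generator that emulates
    a two-session pharmacological prime-flanker experiment with known ground
    truth, so the whole pipeline is testable end to end without access to raw
    recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    generics,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
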