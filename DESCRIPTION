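Package: momentropy
Title: Metastable Oscillatory Modes and Eigenvalue-Spectrum Entropy in
    Delay-Coupled Oscillator Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates networks of Stuart-Landau oscillators coupled through a
    weighted structural connectome with pairwise conduction delays and additive
    complex white noise, detects Metastable Oscillatory Modes (MOMs) as
    coalitions of nodes whose band-limited Hilbert amplitude exceeds a
    no-delay baseline by a multiple of its standard deviation, and tracks
    system-level order through the Shannon entropy of the normalized
    eigenvalue spectrum of sliding-window phase covariance matrices. Includes
    a synthetic-connectome generator, a parameter sweep over global coupling
    and mean delay with Bonferroni-corrected Pearson correlations between
    coalition size and entropy, tidy accessors, and ggplot2 visualisations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
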