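Package: neodev
Title: Analysis of Discontinuous Oscillatory Activity in Neonatal
    Prefrontal-Hippocampal Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying the discontinuous network activity of the
    neonatal rodent brain from multichannel extracellular recordings of the
    prelimbic cortex (PL) and hippocampal CA1 (HP). Implements detection of
    oscillatory active periods with a hysteresis threshold on an RMS boxcar
    envelope, Welch power spectra restricted to active periods, band powers,
    imaginary coherence, phase-amplitude coupling comodulograms, multi-unit
    spike detection with prominence criteria, plug-in entropy and mutual
    information of binned spike trains, behavioral scores (novelty
    discrimination, spontaneous alternation, marble burying, open field,
    scan sampling), and a nonparametric group-comparison battery with
    percentile outlier exclusion. A synthetic-data generator produces
    recordings, spike trains, behavior logs, and whole cohorts with ground
    truth so every stage of the pipeline is testable end to end.
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
    jsonlite,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
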