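Package: waloc
Title: Level-Weighted Averaging Analysis of Double-Sound Localization in Elevation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how listeners localize two synchronous
    broadband sounds in the midsagittal plane. Synthesizes amplitude-modulated
    and flat Gaussian-noise stimuli and analyzes their time-windowed power;
    builds the factorial localization and up/down discrimination trial designs;
    simulates behavioral responses under a level-weighted-average model and
    rival (bistable) models, including raw head-orientation traces; detects
    head saccades with a velocity threshold and applies quality-control
    filters; and fits the localization and discrimination models by Bayesian
    MCMC (Gibbs sampling) with highest-density intervals, Gelman-Rubin
    convergence diagnostics, and Savage-Dickey Bayes factors.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    jsonlite,
    signal,
    withr
Suggests:
    testthat (>= 3.0.0),
    rjags,
    coda
Config/testthat/edition: 3
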