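Package: mdfa
Title: Single- and Multichannel Detrended Fluctuation Analysis for
    Neurophysiological Recordings
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates long-range temporal correlations (Hurst-type scaling
    exponents) in uniformly sampled biomedical time series by detrended
    fluctuation analysis (DFA) with polynomial detrending of arbitrary order,
    and by a multichannel generalization (mDFA) that integrates and detrends
    each channel separately and pools the squared residual fluctuations into
    a single ensemble scaling exponent.  Includes shuffle surrogates for
    randomization controls, Welch-averaged magnitude-squared coherence for
    pairwise cross-checks, paired statistical comparison of fluctuation
    curves across experimental conditions, and a seeded synthetic generator
    of fractional Gaussian noise, 1/f noise, and coupled multichannel cord
    dorsum potential-like signals with a lesionable inter-channel coupling
    structure.  A command-line interface exposes the full analysis workflow
    on delimited-text recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
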