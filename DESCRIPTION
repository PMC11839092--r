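Package: trfcomp
Title: Temporal Response Functions with Binning-Based Nonlinearity
    Compensation for Auditory EEG
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Forward temporal response function (TRF) modelling of
    multichannel EEG responses to continuous speech envelopes, estimated by
    a sparse boosting (coordinate descent) algorithm with a Hamming-window
    basis and cross-validated early stopping.  Implements a binning-based
    detection and compensation method for static nonlinearities in EEG
    recordings, signal-to-noise-ratio and N1/P2 peak evaluation, TRF
    variance profiles, cluster-based spatiotemporal permutation tests,
    Bonferroni-corrected channel tests, and exact-binomial empirical chance
    levels for two-choice behavioural tasks.  A synthetic auditory-EEG
    generator reproduces the design of a two-talker selective-attention
    experiment (64 channels, 100 Hz, two hearing-aid noise-reduction
    conditions) so that the full six-step analysis pipeline is testable
    without access-restricted recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    data.table
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
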