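Package: statedyn
Title: Latent Oscillatory State Dynamics in Multichannel Neural Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Discovery and characterisation of transient oscillatory brain
    states in trial-wise multichannel source signals. Implements time-delay
    embedding with PCA compression, a K-state hidden Markov model with a
    zero-mean Gaussian (autocovariance) observation model fitted by
    expectation-maximisation, forward-backward and Viterbi decoding, state
    dynamics metrics (fractional occupancy, lifetimes, switching rate),
    state-wise cross-spectral power and phase coherence with non-negative
    matrix factorisation into frequency modes, condition decoding from state
    occupancies, pairwise Granger causality by BIC model comparison, evoked
    response summaries with cluster-based permutation testing, and gamma
    generalised linear models linking state dynamics to behavioural
    durations. Includes a synthetic-data generator that plants known state
    sequences, spectral signatures, directed couplings and behavioural
    effects for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    e1071
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
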