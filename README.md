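# statedyn

Latent oscillatory state dynamics in multichannel neural time series.

## What this package is for

During bistable perception (e.g. binocular rivalry) the percept alternates
while the stimulus does not, so the trigger of an upcoming perceptual
transition must be endogenous. `statedyn` provides a complete, tested
pipeline for asking whether transient oscillatory brain states in
source-level EEG anticipate such transitions. It is aimed at researchers
working with trial-segmented multichannel source signals (regions of
interest × time × trials) who want to:

1. **discover states** with a time-delay embedded hidden Markov model
   (TDE-HMM): frames stack every channel at lags −w..+w (60 ms window by
   default), are compressed by PCA, and are modelled by K zero-mean
   Gaussians with full covariance — so each state encodes a lagged
   auto/cross-covariance pattern, i.e. band-limited power and cross-channel
   phase-locking, not a voltage level;
2. **characterise states spectrally**: state-conditioned Welch
   cross-spectra give per-state power and phase coherence
   `|S_k(i,j,f)| / sqrt(S_k(i,i,f) S_k(j,j,f))`, and non-negative matrix
   factorisation of the concatenated coherence spectra yields data-driven
   frequency modes (theta, alpha, beta, ...) with peak and half-maximum
   frequencies;
3. **relate states to behaviour**: fractional occupancy (FO), state
   lifetimes and switching rates; pairwise occupancy permutation tests with
   FDR control; cross-validated linear-SVM decoding of the upcoming percept
   type from trial-wise FO over a 26-point regularisation grid;
4. **estimate directed coupling** by Granger causality as BIC model
   comparison: dBIC = mean over p = 1..20 of BIC(target-only AR at its best
   order) − BIC(AR augmented with source lags j = 0..p); positive = causal
   evidence;
5. **model percept durations** with gamma GLMs (log link):
   `duration ~ state lifetime × dBIC`, with ΔAIC and Cohen's f² for the
   interaction;

plus sensor-style evoked summaries (baseline-corrected epochs, global field
power, 1-D cluster-based sign-flip permutation tests) and a synthetic-data
generator (`simulate_study()`) that plants known states, spectral
signatures, directed couplings and behavioural effects so every stage can
be validated end to end.

## Worked example

```r
library(statedyn)

sim  <- simulate_study(n_trials = 200, seed = 42)   # planted ground truth
sim$trials
#> <trialset> 200 trials x 275 samples x 8 channels @ 250 Hz
#>   channels: lHP, rHP, lIPL, rIPL, ACC, PCC, PCU, V1
#>   conditions: BR_dom(61) BR_mix(45) RPL_dom(55) RPL_mix(39)
#>   subjects: 20

pipe <- fit_state_pipeline(sim$trials)   # embed -> PCA -> HMM -> decode
pipe$model
#> <state_model> K = 4, dim = 16, loglik = -1747746.47 (converged, 25 iterations)

# how well are the planted states recovered, frame by frame?
w     <- pipe$embedding$w
truth <- as.vector(t(sim$truth$paths$paths[, (w + 1):(275 - w)]))
match_paths(pipe$posterior$viterbi, truth, K = 4)$accuracy
#> 0.889

# decode the upcoming percept type (dominant vs mixed) within rivalry trials
br <- sim$trials$condition %in% c("BR_dom", "BR_mix")
crossval_decode(pipe$metrics$fo[br, ], droplevels(sim$trials$condition[br]),
                seed = 1)
#> <decode_result> 5-fold CV over 26 grid values, n = 106
#>   best: 90.52% (SD 4.82%) at cost 0.631; converged: 89.30%

# frequency modes of the state coherence spectra
s <- state_cross_spectra(sim$trials, pipe$posterior)
nnmf_modes(coherence_features(s), 4, freq = s$freq, seed = 1)
#> <frequency_modes> 4 modes, relative error 0.185
#>   mode 1: peak 4 Hz, half-maximum [2, 6] Hz
#>   mode 2: peak 10 Hz, half-maximum [8, 14] Hz
#>   mode 3: peak 20 Hz, half-maximum [18, 22] Hz
#>   mode 4: peak 26 Hz, half-maximum [24, 44] Hz

# does the gating state's lifetime interact with the directed coupling?
fit_interaction_glm(sim$behavior)
#> <glm_fit> gamma/log trial-level, n = 200, AIC = 596.60, f2 = 0.009
#>             estimate     se       t      p
#> (Intercept)   0.8621 0.0935  9.2190 0.0000
#> lifetime     -0.4735 0.2105 -2.2495 0.0256
#> gc           -0.1069 0.0786 -1.3594 0.1756
#> lifetime:gc  -0.2888 0.1989 -1.4519 0.1481
```

Reading the output: state recovery of 88.9% means the Viterbi path agrees
with the planted state sequence on that fraction of frames after optimal
relabelling; the decoder separates upcoming dominant from mixed percepts at
~90% because the generator biases each condition's occupancy towards an
indicative state; the NNMF modes land on the planted theta (4 Hz), alpha
(11 Hz, read off the 2-Hz grid) and beta (20 Hz) bands; and the gamma GLM
estimates the planted negative lifetime × coupling interaction (−0.4) with
the expected uncertainty at n = 200.

A command-line wrapper over the same functions lives at
`inst/cli/statedyn.R` (subcommands `simulate`, `evoked`, `fit-hmm`,
`spectra`, `decode`, `gc`, `behavior`, `report`; every run logs its config
hash and seed).

## Documentation

Every exported function carries roxygen documentation, and
`vignettes/state-dynamics.Rmd` explains the models, the tunable parameters
and their defaults, what the synthetic generator does and does not emulate,
and the numerical design choices (initialisation, convergence,
regularisation, tie-breaking, degenerate inputs).
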