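---
title: "Latent oscillatory state dynamics: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent oscillatory state dynamics: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(statedyn)
```

## The problem

During binocular rivalry the percept alternates while the stimulus does not,
so whatever triggers an upcoming perceptual transition must be endogenous.
`statedyn` implements a pipeline for asking whether transient oscillatory
states in source-level EEG — here eight regions: bilateral parahippocampal
gyri and inferior parietal lobules, anterior and posterior cingulate,
precuneus (PCU) and primary visual cortex (V1) — anticipate the type of the
upcoming percept in the second before the behavioural report. The pipeline
has five stages: state discovery (time-delay embedded HMM), state spectral
characterisation (conditioned cross-spectra and their non-negative
factorisation into frequency modes), condition-level inference (occupancy
tests and decoding), directed coupling (Granger causality by BIC
comparison), and behavioural linkage (gamma GLMs of percept duration).

## The observation model: autocovariance, not amplitude

A hidden Markov model on raw channel amplitudes would segment the data by
mean level, which is the wrong currency for oscillations: the information
sits in frequencies and phase relations. The time-delay embedding fixes
this. With a window of $L$ samples (default 60 ms at 250 Hz, so $L = 15$,
half-window $w = 7$), the frame at sample $t$ stacks all channels at lags
$-w..+w$, a vector of $L \times C = 120$ dimensions for $C = 8$ channels.
The sample covariance of these frames is the channels' lagged
auto/cross-covariance over the window, so a zero-mean Gaussian with full
covariance fitted to the embedded frames describes an oscillatory spectral
signature — band-limited power and cross-channel phase-locking — rather
than a voltage level. The observation mean is fixed at zero: epochs are
baseline-corrected and the model is meant to capture second-order structure
only.

Embedded frames are compressed by PCA to `n_pcs` dimensions before
inference (default 16, twice the channel count — enough to hold each
channel's dominant rhythm plus cross-channel structure while regularising
the 120-dimensional state covariances). Edge samples without a full window
are dropped: a 275-sample trial yields 261 frames, and no frame spans a
trial boundary.

## Inference

`fit_hmm()` runs expectation–maximisation with exact forward–backward
E-steps computed per trial: the chain restarts from the initial
distribution at every trial boundary and expected transition counts never
cross trials. Numerical and procedural choices:

* **Restarts.** Five random initialisations (per-frame Dirichlet(1)
  responsibilities), each seeded deterministically from the stage seed; the
  best final log-likelihood wins, ties broken by restart index.
* **Convergence.** Relative log-likelihood change below $10^{-6}$, capped
  at 500 iterations; non-convergence returns a flagged model with a
  warning rather than an error.
* **Covariance collapse.** If a state covariance's condition number
  exceeds $10^{12}$ it receives a ridge of $10^{-6}$ times its mean
  diagonal, and the model records that regularisation happened.
* **Exactness.** Forward–backward and Viterbi are validated against
  exhaustive enumeration over all $K^T$ paths on small random instances
  (up to 6 frames, 3 states, 1000 cases in the test suite) — an oracle
  implemented independently in plain R.

Full-data EM was preferred over stochastic variational updates: at the
problem sizes this package targets (≤ a few hundred thousand frames) a full
pass is cheap, and determinism given the seed makes every result in the
test suite reproducible. A Dirichlet(1) prior on transition rows leaves
the M-step at its maximum-likelihood form.

State metrics come from the Viterbi path, not the soft posteriors:
fractional occupancy (FO) is the fraction of a trial's frames in each
state, a lifetime is one maximal dwell (in seconds), and the switching
rate is state changes per second. Hard assignment keeps the three
mutually consistent — per state, lifetimes sum to FO × trial duration
exactly — which soft occupancy cannot guarantee. Soft occupancies remain
available from the `gamma` matrix for users who want them.

## State spectra and frequency modes

`state_cross_spectra()` conditions a Welch estimator on the states: 0.5-s
Hann-tapered segments with 50% overlap, each segment's periodogram
cross-product weighted by the state's mean posterior probability over the
segment. Because per-segment weights sum to one across states, the
weighted average of the state cross-spectra reproduces the unconditional
cross-spectrum exactly — an identity asserted in the tests. Welch
segments were chosen over a multitaper for determinism and transparency at
desk scale; the estimator name is recorded in the output. The 0.5-s
segment gives a 2-Hz frequency resolution on the default 1–45 Hz grid,
wide enough to separate theta/alpha/beta modes while keeping several
segments per trial. An alternative would have been to derive spectra
analytically from the fitted state covariances; the weighted-periodogram
route was preferred because it stays interpretable when the model is
misspecified, and the choice is named in the output metadata.

Coherence spectra of all states and channel pairs are concatenated into a
frequencies × (states · pairs) matrix and factorised by multiplicative-
update NNMF (Frobenius loss, 10 restarts, best reconstruction kept) into a
small number of non-negative spectral profiles — data-driven frequency
bands summarised by their peak and half-maximum frequencies. Mode count
defaults to four, matching the canonical theta/alpha/beta/gamma
decomposition.

Per-feature state specificity is tested by permutation: state labels are
shuffled within trials across the per-trial state-conditional estimates,
giving one-tailed p-values in each direction at a default
$\alpha = 0.01$ with 5000 permutations.

## Condition-level inference

Occupancy differences are tested within each condition for every state
pair with a median-difference permutation test whose null swaps the two
states' values independently per unit — under the null hypothesis the two
states' occupancies are exchangeable. Units are subjects (per-subject mean
FO) when subject identifiers are available, trials otherwise;
Benjamini–Hochberg adjustment runs across all condition × pair
comparisons (2000 permutations by default).

Decoding uses a linear support-vector classifier on trial-wise FO vectors
with stratified 5-fold cross-validation over a fixed cost grid,
$10^{-5}$ to $10^{0}$ in steps of 0.2 on the log10 scale (26 values). Two
summaries are reported because "the" CV accuracy is ambiguous: the best
grid accuracy, and a converged accuracy — the mean over the contiguous
upper tail of the grid whose accuracies stay within one fold-SE of the
maximum. Chance calibrations in the tests use balanced class subsets so
that 0.5 is the correct reference level.

Half-split reliability refits the model on random subject halves,
matches states across fits by Pearson correlation of vectorised state
covariances with exact optimal assignment (all $K!$ permutations scored;
$K$ is small), and contrasts matched against unmatched similarities
across repeats (5 by default).

## Granger causality by BIC comparison

For a directed pair (source $X_2$, target $X_1$), the null model is the
target's own autoregression
$X_1(t) = \sum_{j=1}^{p} b_{11,j} X_1(t-j) + E_1(t)$ at the order
$p^* \in 1..p_{\max}$ minimising BIC; the augmented model adds
$\sum_{j=0}^{p} b_{12,j} X_2(t-j)$. The instantaneous $j = 0$ term is
included by default because the augmented formulation starts its sum at
zero; `include_instantaneous = FALSE` restores the conventional
lag-only form. The effect size is
$\mathrm{dBIC} = \mathrm{mean}_p\,[\mathrm{BIC}_{null}(p^*) -
\mathrm{BIC}_{aug}(p)]$ over $p = 1..p_{\max}$ (default 20 lags = 80 ms at
250 Hz); positive values mean the source's past improves the evidence.

One numerical subtlety: all candidate models within one comparison are fit
on a common effective sample, $t = p_{\max}+1..T$. If instead each model
used its own truncation $t = p+1..T$, the BIC scale shift under a common
rescaling of both series, $(T-p)\ln c^2$, would differ across lags —
changing $p^*$ and the dBIC with the units of the data. With a common
sample the shift cancels and dBIC is exactly scale-invariant, which the
tests assert numerically. Trials are analysed separately and demeaned
(not detrended) before fitting; $p^*$ is chosen per trial.

Averaging dBIC over $p$ up to 20 makes the statistic conservative on
short trials: the augmented model carries $2p+1$ coefficients, so at a
275-sample trial the penalty term dominates at large $p$ and even a real
lag-2 coupling yields a negative average — while remaining robustly
larger than the reverse direction. The directional contrast, not the raw
sign, is therefore the meaningful readout at trial length; the raw sign
becomes informative on long series.

## Behavioural linkage

Percept durations are positive and right-skewed, so duration models use a
gamma GLM with log link: `duration ~ lifetime * gc`, at trial level or on
subject means (the unit for population-level claims). The interaction
effect is summarised three ways: its coefficient with Wald statistics,
$\Delta\mathrm{AIC}$ against the no-interaction model (positive favours
the interaction), and Cohen's $f^2$ on deviance-based $R^2$. Duration
summaries report the adjusted Fisher–Pearson skewness and *excess*
kurtosis — the convention under which a normal distribution scores 0 —
matching how heavy-tailed percept-duration distributions are conventionally
reported. Individual differences are handled in the simplest form that
supports the question: fixed subject intercepts against a pooled
intercept, compared by AIC and a deviance $\chi^2$.

## What the synthetic generator emulates — and what it does not

`simulate_study()` plants everything the pipeline is supposed to find:

* a first-order hidden Markov chain per trial (K = 4), with self-transition
  probabilities giving ~200-ms mean dwells; first-order rather than
  semi-Markov, so state recovery is a well-posed self-consistency check
  against the model class the pipeline fits;
* condition-dependent occupancy: each of the four conditions biases its
  indicative state (BR-dominant → state 4, BR-mixed → 3, RPL-dominant → 2,
  RPL-mixed → 1) through the initial distribution and transition matrix
  only — state signatures themselves are condition-invariant;
* state-specific oscillatory signatures (defaults in
  `default_state_spec()`): broad high-power alpha (state 1), beta-dominant
  with weak uncoupled alpha (state 2), theta coherence across the midline
  nodes (state 3), and alpha-band phase coupling of PCU with V1 and the
  right IPL (state 4). Oscillator phases are redrawn at every dwell;
  within a dwell a coupled pair keeps a fixed phase difference, which is
  exactly what phase-coherence detection requires;
* 1/f (power exponent 1, by spectral shaping of white noise) plus white
  noise per channel. The default noise scale (SD 0.35 each against unit-
  order oscillation amplitudes) was calibrated once so that the default
  conditions support ≥ 0.85 frame-wise state recovery, and left alone;
* an optional lagged PCU → V1 coupling (default lag 2 samples, gain 0.5)
  active only on frames of the gating state — ground truth for the
  Granger stage;
* percept durations from the gamma interaction GLM with default
  coefficients $(b_0, b_1, b_2, b_3) = (0.8, -0.38, -0.1, -0.4)$ and shape
  2, using the gating state's true lifetime per trial. Shape 2 gives
  skewness $2/\sqrt{2} \approx 1.4$, in the right regime for heavy-tailed
  percept durations; $\exp(b_0) \approx 2.2$ s matches typical dominant-
  percept medians. Trials are apportioned across the four conditions with
  the epoch proportions of the emulated study (7795/7148/5786/5038 of
  25767) over 20 subjects.

It does **not** emulate: volume conduction or any forward-model mixing
(channels are sources, not sensors), artefacts (ocular, cardiac, motion),
non-stationary spectra within a dwell, semi-Markov dwell distributions, or
between-subject variability in the state signatures. Passing tests on this
generator therefore demonstrate internal consistency of the pipeline —
that it recovers what its own model class can represent at realistic SNR —
not that real EEG satisfies those assumptions.

All randomness flows from one global seed; each stage derives a child seed
deterministically from (seed, stage name) via `derive_seed()`, so the same
configuration reproduces bit-identical data while stages stay decoupled.

## Interpreting the GLM recovery checks

The test suite checks the behavioural GLM by coverage: across 100
replicates at n = 2000, each generator coefficient must fall inside its
95% Wald CI in at least 90% of replicates, assessed per coefficient. The
per-coefficient criterion is the quantity CI calibration controls
(nominally 95%); the joint event — all four coefficients covered at once —
has probability equal to a four-dimensional orthant integral that
correct CIs do not control (empirically ~0.83–0.89 here depending on the
covariate design), so it is deliberately not the acceptance quantity.

## Problem sizes and defaults in the test suite

The suite exercises the full default conditions — 500 trials × 275
samples × 8 channels, K = 4, 16 PCs, 5 restarts — once, shared across the
end-to-end checks; calibration runs use 60–200 simulations with 200–1000
permutations each, and the HMM oracle checks 1000 random small instances.
These sizes were chosen so the whole suite completes in a few minutes
while keeping every Monte-Carlo margin several standard errors wide.

## Known limitations

* The HMM assumes stationary Gaussian emissions within a state; drifting
  amplitude within a dwell blurs state boundaries.
* Welch conditioning attributes a whole 0.5-s segment to states in
  proportion to its average posterior, so states shorter than a segment
  leak spectrally into their neighbours.
* The Granger stage is bivariate: common input from a third region can
  masquerade as directed coupling, and the instantaneous term (included
  by default) absorbs zero-lag correlation rather than attributing it a
  direction.
* Decoding accuracy on FO features is an association measure; it does not
  by itself separate anticipation from leakage of post-decision processes
  into the pre-report window.
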