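#' Sample hidden Markov state paths
#'
#' Draws one independent first-order Markov chain per trial. The initial
#' state of each trial comes from that trial's row of `init`, so condition-
#' dependent occupancy can be planted through condition-specific initial
#' distributions and transition matrices.
#'
#' @param transition K x K row-stochastic matrix, or a list of per-trial
#'   matrices (length `n_trials`).
#' @param init Length-K initial distribution, or an `n_trials` x K matrix of
#'   per-trial initial distributions.
#' @param n_trials,n_samples Number of chains and chain length.
#' @param seed Integer seed.
#' @return A `state_path_truth` list: `paths` (n_trials x n_samples integer
#'   matrix over 1..K), `transition`, `init`.
#' @export
sample_state_paths <- function(transition, init, n_trials, n_samples, seed = 1L) {
  if (n_samples < 1) stop("n_samples must be >= 1")
  per_trial <- is.list(transition)
  check_stoch <- function(A) {
    if (any(A < 0) || any(abs(rowSums(A) - 1) > 1e-12))
      stop("transition matrix rows must be non-negative and sum to 1")
    A
  }
  if (per_trial) lapply(transition, check_stoch) else check_stoch(transition)
  K <- if (per_trial) nrow(transition[[1]]) else nrow(transition)
  if (is.null(dim(init))) init <- matrix(init, n_trials, K, byrow = TRUE)
  if (any(abs(rowSums(init) - 1) > 1e-9)) stop("initial distributions must sum to 1")
  paths <- matrix(0L, n_trials, n_samples)
  with_seed(seed, {
    for (i in seq_len(n_trials)) {
      A <- if (per_trial) transition[[i]] else transition
      s <- sample.int(K, 1L, prob = init[i, ])
      paths[i, 1L] <- s
      if (n_samples > 1L) {
        u <- stats::runif(n_samples - 1L)
        cum <- t(apply(A, 1, cumsum))
        for (j in 2:n_samples) {
          s <- findInterval(u[j - 1L], cum[s, ]) + 1L
          paths[i, j] <- s
        }
      }
    }
  })
  structure(list(paths = paths, transition = transition, init = init),
            class = "state_path_truth")
}

#' Oscillatory state signature specification
#'
#' Describes, for each hidden state, the band-limited oscillatory components
#' that the generator renders while the state is active. Each component has
#' a centre frequency, per-channel amplitudes, and optional coupling sets:
#' groups of channels that share one oscillator (a common dwell-wise random
#' phase) with fixed per-channel phase lags, mixed with an independent
#' per-channel oscillator according to a coupling strength in [0, 1]
#' (1 = fully phase-locked, 0 = independent phases).
#'
#' @param states A list of length K; each element a list of components. A
#'   component is `list(freq =, amp = named or full-length vector, couple =
#'   list(list(channels =, lags =, strength = )))`.
#' @param noise_sd White-noise standard deviation per channel (recycled).
#' @param pink_sd 1/f (power exponent 1) noise standard deviation per channel.
#' @param channels Channel labels the amplitudes refer to.
#' @return A `state_spec` object.
#' @export
state_spec <- function(states, noise_sd = 0.35, pink_sd = 0.35,
                       channels = default_channels()) {
  C <- length(channels)
  noise_sd <- rep(noise_sd, length.out = C)
  pink_sd <- rep(pink_sd, length.out = C)
  if (any(noise_sd < 0) || any(pink_sd < 0)) stop("noise sd must be >= 0")
  for (st in states) for (comp in st) {
    if (comp$freq <= 0) stop("component frequencies must be positive")
    if (any(comp$amp < 0)) stop("amplitudes must be >= 0")
    for (cp in comp$couple %||% list())
      if (cp$strength < 0 || cp$strength > 1) stop("coupling strength must lie in [0,1]")
  }
  structure(list(states = states, noise_sd = noise_sd, pink_sd = pink_sd,
                 channels = channels), class = "state_spec")
}

#' The eight analysis channels
#'
#' Default-mode-network source regions (bilateral parahippocampal gyri and
#' inferior parietal lobules, anterior/posterior cingulate, precuneus)
#' plus primary visual cortex.
#' @return Character vector of length 8.
#' @export
default_channels <- function() c("lHP", "rHP", "lIPL", "rIPL", "ACC", "PCC", "PCU", "V1")

# expand a component amplitude spec to a full per-channel vector
expand_amp <- function(amp, channels) {
  C <- length(channels)
  if (is.null(names(amp))) return(rep(amp, length.out = C))
  out <- numeric(C); names(out) <- channels
  out[names(amp)] <- amp
  out
}

#' Default planted state signatures
#'
#' Four states emulating the condition-indicative oscillatory patterns of
#' the bistable-perception study: state 1, high alpha (11 Hz) power across
#' all channels with independent phases; state 2, moderate alpha plus a
#' distinguishing beta (20 Hz) component, with the precuneus-V1 pair left
#' uncoupled; state 3, theta (4 Hz) coherence across the midline
#' default-mode nodes (ACC-PCC and neighbours); state 4, alpha-band phase
#' coupling of the precuneus with V1 and the right inferior parietal lobule.
#'
#' @param alpha_hz,theta_hz,beta_hz Band centre frequencies (Hz).
#' @param coupling_strength Phase-coupling strength of the planted coupled
#'   sets, in [0, 1].
#' @return A `state_spec` for [synthesize_signals()].
#' @export
default_state_spec <- function(alpha_hz = 11, theta_hz = 4, beta_hz = 20,
                               coupling_strength = 0.9) {
  ch <- default_channels()
  states <- list(
    # state 1: strong broad alpha power, phases independent
    list(list(freq = alpha_hz, amp = rep(1.6, 8))),
    # state 2: weak alpha + dominant beta; PCU-V1 deliberately uncoupled
    list(list(freq = alpha_hz, amp = rep(0.4, 8)),
         list(freq = beta_hz, amp = rep(1.3, 8))),
    # state 3: theta coherence among midline DMN nodes
    list(list(freq = theta_hz, amp = rep(1.2, 8),
              couple = list(list(channels = c("ACC", "PCC", "PCU", "lIPL", "rIPL"),
                                 lags = c(0, pi / 6, pi / 3, pi / 2, 2 * pi / 3),
                                 strength = coupling_strength)))),
    # state 4: alpha phase coupling PCU-V1 and PCU-rIPL
    list(list(freq = alpha_hz, amp = rep(1.0, 8),
              couple = list(list(channels = c("PCU", "V1", "rIPL"),
                                 lags = c(0, pi / 4, pi / 2),
                                 strength = coupling_strength))))
  )
  state_spec(states, channels = ch)
}

# 1/f noise of length n via spectral shaping of white noise;
# power spectrum proportional to 1/f, scaled to standard deviation sd
pink_noise <- function(n, sd) {
  if (sd == 0) return(numeric(n))
  white <- stats::rnorm(n)
  spec <- stats::fft(white)
  f <- c(1, seq_len(n - 1))
  f <- pmin(f, n - f + 1)                 # fold to two-sided frequencies
  spec <- spec / sqrt(f)
  x <- Re(stats::fft(spec, inverse = TRUE)) / n
  x <- x - mean(x)
  x / stats::sd(x) * sd
}

#' Render multichannel signals from hidden state paths
#'
#' Within every maximal dwell segment of state k, each oscillatory component
#' of that state contributes `amp * cos(2 pi f t + phase)` per channel.
#' Channels inside a coupling set share one random phase (plus the
#' specified per-channel lag) with weight `sqrt(strength)`, blended with an
#' independent random phase with weight `sqrt(1 - strength)`, so the
#' planted magnitude-squared coherence at the component frequency equals
#' the coupling strength squared over variance terms (1 at strength 1, 0 at
#' strength 0). Phases are redrawn at every dwell segment; within a dwell
#' they are constant, which is what phase-coherence detection requires.
#' White and 1/f noise are added per channel.
#'
#' @param paths A `state_path_truth` (or integer matrix of paths).
#' @param spec A `state_spec`.
#' @param fs Sampling rate, Hz.
#' @param condition,subject,event_sample Passed through to [trialset()].
#' @param seed Integer seed.
#' @return A [trialset()].
#' @export
synthesize_signals <- function(paths, spec, fs,
                               condition = NULL, subject = NULL,
                               event_sample = NULL, seed = 1L) {
  pm <- if (inherits(paths, "state_path_truth")) paths$paths else paths
  n_trials <- nrow(pm); n_samples <- ncol(pm)
  ch <- spec$channels; C <- length(ch)
  for (st in spec$states) for (comp in st)
    if (comp$freq >= fs / 2) stop("component frequency at or above Nyquist")
  condition <- condition %||% rep("BR_dom", n_trials)
  subject <- subject %||% rep("S01", n_trials)
  event_sample <- event_sample %||% n_samples
  tt <- (seq_len(n_samples) - 1) / fs
  data <- array(0, dim = c(n_trials, n_samples, C))
  with_seed(seed, {
    for (i in seq_len(n_trials)) {
      x <- matrix(0, n_samples, C)
      path <- pm[i, ]
      # maximal dwell segments
      bounds <- c(0L, which(diff(path) != 0L), n_samples)
      for (b in seq_len(length(bounds) - 1L)) {
        idx <- (bounds[b] + 1L):bounds[b + 1L]
        k <- path[idx[1L]]
        for (comp in spec$states[[k]]) {
          amp <- expand_amp(comp$amp, ch)
          omega <- 2 * pi * comp$freq
          coupled <- rep(FALSE, C)
          for (cp in comp$couple %||% list()) {
            j <- match(cp$channels, ch)
            if (anyNA(j)) stop("unknown channel in coupling set")
            coupled[j] <- TRUE
            shared <- stats::runif(1, 0, 2 * pi)
            s <- cp$strength
            for (m in seq_along(j)) {
              own <- stats::runif(1, 0, 2 * pi)
              x[idx, j[m]] <- x[idx, j[m]] + amp[j[m]] *
                (sqrt(s) * cos(omega * tt[idx] + shared + cp$lags[m]) +
                 sqrt(1 - s) * cos(omega * tt[idx] + own))
            }
          }
          for (c0 in which(!coupled & amp > 0)) {
            own <- stats::runif(1, 0, 2 * pi)
            x[idx, c0] <- x[idx, c0] + amp[c0] * cos(omega * tt[idx] + own)
          }
        }
      }
      for (c0 in seq_len(C)) {
        if (spec$noise_sd[c0] > 0)
          x[, c0] <- x[, c0] + stats::rnorm(n_samples, sd = spec$noise_sd[c0])
        if (spec$pink_sd[c0] > 0)
          x[, c0] <- x[, c0] + pink_noise(n_samples, spec$pink_sd[c0])
      }
      data[i, , ] <- x
    }
  })
  trialset(data, fs = fs, channels = ch, condition = condition,
           subject = subject, event_sample = event_sample)
}

#' Inject a lagged directed coupling between two channels
#'
#' Adds `gain * src(t - lag)` to the destination channel, optionally only on
#' frames whose hidden state equals `gate` — the planted ground truth that
#' the Granger-causality stage is expected to recover (and, when gated, to
#' lose on frames of the other states).
#'
#' @param t A `trialset`.
#' @param src,dst Channel labels (must differ).
#' @param lag Positive lag in samples, smaller than the trial length.
#' @param gain Coupling gain.
#' @param gate Integer state whose frames carry the coupling, or `NULL` for
#'   all frames.
#' @param paths State paths (matrix or `state_path_truth`); required if
#'   `gate` is not `NULL`.
#' @return A modified `trialset`; the source channel is unchanged.
#' @export
inject_lagged_coupling <- function(t, src, dst, lag, gain, gate = NULL, paths = NULL) {
  if (identical(src, dst)) stop("src and dst must differ")
  is_ <- match(src, t$channels); id <- match(dst, t$channels)
  if (anyNA(c(is_, id))) stop("unknown channel label")
  n_samples <- dim(t$data)[2]
  if (lag <= 0 || lag >= n_samples) stop("lag must satisfy 0 < lag < trial length")
  if (!is.null(gate)) {
    pm <- if (inherits(paths, "state_path_truth")) paths$paths else paths
    if (is.null(pm)) stop("paths required when gate is set")
  }
  sl <- (lag + 1L):n_samples
  for (i in seq_len(dim(t$data)[1])) {
    add <- gain * t$data[i, sl - lag, is_]
    if (!is.null(gate)) add <- add * (pm[i, sl] == gate)
    t$data[i, sl, id] <- t$data[i, sl, id] + add
  }
  t
}

#' Sample behavioural durations from a gamma GLM
#'
#' Durations are drawn from a gamma distribution with the given shape and
#' mean `exp(b0 + b1 * lifetime + b2 * gc + b3 * lifetime * gc)` (log link),
#' the generative counterpart of the behavioural-relevance model: a negative
#' interaction `b3` makes the directed-coupling effect shorten percept
#' durations more strongly on trials where the gating state persists longer.
#'
#' @param lifetimes Per-trial state lifetime (s), >= 0.
#' @param gc Per-trial directed-coupling effect size (dBIC scale).
#' @param coef Numeric `c(b0, b1, b2, b3)` on the log link.
#' @param shape Gamma shape parameter (> 0).
#' @param seed Integer seed.
#' @return A data frame with columns `duration`, `lifetime`, `gc`.
#' @export
sample_behavior <- function(lifetimes, gc, coef = c(0.8, -0.38, -0.1, -0.4),
                            shape = 2, seed = 1L) {
  if (shape <= 0) stop("gamma shape must be positive")
  if (any(lifetimes < 0)) stop("lifetimes must be >= 0")
  stopifnot(length(lifetimes) == length(gc), length(coef) == 4L)
  mu <- exp(coef[1] + coef[2] * lifetimes + coef[3] * gc +
            coef[4] * lifetimes * gc)
  dur <- with_seed(seed, stats::rgamma(length(mu), shape = shape, rate = shape / mu))
  data.frame(duration = dur, lifetime = lifetimes, gc = gc)
}

# per-condition transition matrix: the indicative state is sticky and
# preferentially entered, planting the condition-occupancy bias
condition_transition <- function(K, indicative, self_ind = 0.985,
                                 self_other = 0.96, entry_bias = 0.5) {
  A <- matrix(0, K, K)
  for (i in seq_len(K)) {
    self <- if (i == indicative) self_ind else self_other
    rest <- 1 - self
    others <- setdiff(seq_len(K), i)
    w <- rep(1, length(others))
    if (indicative %in% others && K > 2)
      w[others == indicative] <- entry_bias * (K - 2) / (1 - entry_bias)
    A[i, others] <- rest * w / sum(w)
    A[i, i] <- self
  }
  A
}

#' Generate a complete synthetic study
#'
#' End-to-end generator for pipeline validation: trials are apportioned
#' across the four conditions with the study's epoch proportions and spread
#' over subjects; each condition's hidden chain is biased towards its
#' indicative state (BR_dom -> 4, BR_mix -> 3, RPL_dom -> 2, RPL_mix -> 1);
#' signals carry the [default_state_spec()] oscillatory signatures; an
#' optional lagged precuneus -> V1 coupling is injected on frames of the
#' gating state; and per-trial percept durations are drawn from the gamma
#' interaction GLM using the gating state's true total lifetime.
#'
#' @param n_trials Total number of trials.
#' @param n_subjects Number of subjects (trials spread round-robin).
#' @param n_samples Samples per trial (default 275 = 1 s pre-response +
#'   100 ms padding at 250 Hz).
#' @param fs Sampling rate (Hz).
#' @param spec A `state_spec` (default [default_state_spec()]).
#' @param condition_bias If `FALSE`, all conditions share one unbiased
#'   chain (negative control for decoding).
#' @param gc_lag,gc_gain Lag (samples) and gain of the planted PCU -> V1
#'   coupling; `gc_gain = 0` disables it.
#' @param gc_gate State gating the coupling (default 4).
#' @param behavior_coef,behavior_shape Parameters of [sample_behavior()].
#' @param seed Global seed; stages use [derive_seed()] children.
#' @return A list: `trials` (a [trialset()]), `truth` (list with `paths`,
#'   `spec`, `indicative`, `gc = list(src, dst, lag, gain, gate)`,
#'   `behavior = list(coef, shape)`), and `behavior` (data frame from
#'   [sample_behavior()] plus subject and condition columns).
#' @export
simulate_study <- function(n_trials = 500, n_subjects = 20, n_samples = 275,
                           fs = 250, spec = default_state_spec(),
                           condition_bias = TRUE,
                           gc_lag = 2, gc_gain = 0.5, gc_gate = 4,
                           behavior_coef = c(0.8, -0.38, -0.1, -0.4),
                           behavior_shape = 2, seed = 1L) {
  K <- length(spec$states)
  counts <- study_epoch_counts()
  n_cond <- round(n_trials * counts / sum(counts))
  n_cond[1] <- n_trials - sum(n_cond[-1])
  condition <- rep(names(n_cond), n_cond)
  subject <- sprintf("S%02d", rep_len(seq_len(n_subjects), n_trials))
  indicative <- c(BR_dom = 4L, BR_mix = 3L, RPL_dom = 2L, RPL_mix = 1L)
  if (condition_bias) {
    trans <- lapply(condition, function(cd)
      condition_transition(K, indicative[[cd]]))
    init <- t(vapply(condition, function(cd) {
      p <- rep((1 - 0.55) / (K - 1), K); p[indicative[[cd]]] <- 0.55; p
    }, numeric(K)))
  } else {
    trans <- condition_transition(K, 1L, self_ind = 0.96, entry_bias = 1 / (K - 1))
    init <- matrix(1 / K, n_trials, K)
  }
  paths <- sample_state_paths(trans, init, n_trials, n_samples,
                              seed = derive_seed(seed, "paths"))
  trials <- synthesize_signals(paths, spec, fs, condition = condition,
                               subject = subject,
                               event_sample = n_samples - round(0.1 * fs),
                               seed = derive_seed(seed, "signals"))
  if (gc_gain != 0)
    trials <- inject_lagged_coupling(trials, "PCU", "V1", lag = gc_lag,
                                     gain = gc_gain, gate = gc_gate,
                                     paths = paths)
  lifetimes <- rowSums(paths$paths == gc_gate) / fs
  gc_cov <- with_seed(derive_seed(seed, "gc_covariate"),
                      stats::rnorm(n_trials, mean = 0.5, sd = 1))
  behavior <- sample_behavior(lifetimes, gc_cov, coef = behavior_coef,
                              shape = behavior_shape,
                              seed = derive_seed(seed, "behavior"))
  behavior$subject <- subject
  behavior$condition <- condition
  list(trials = trials,
       truth = list(paths = paths, spec = spec, indicative = indicative,
                    gc = list(src = "PCU", dst = "V1", lag = gc_lag,
                              gain = gc_gain, gate = gc_gate),
                    behavior = list(coef = behavior_coef, shape = behavior_shape)),
       behavior = behavior)
}
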