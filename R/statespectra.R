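#' State-wise cross-spectra, power and phase coherence
#'
#' Welch-style estimator conditioned on the hidden states: each trial is cut
#' into Hann-tapered, demeaned, overlapping segments restricted to the
#' samples for which state posteriors exist; segment periodogram
#' cross-products are averaged with weights equal to each state's mean
#' posterior probability (gamma) over the segment. For state k,
#' `S_k(f) = sum_seg w_k,seg X_seg(f) X_seg(f)* / sum_seg w_k,seg`, power is
#' the real diagonal (signal units^2 / Hz) and phase coherence
#' `|S_k(i,j,f)| / sqrt(S_k(i,i,f) S_k(j,j,f))`. Because the per-segment
#' state weights sum to one, the gamma-weighted average of the state
#' cross-spectra reproduces the unconditional cross-spectrum exactly.
#'
#' @param t A [trialset()].
#' @param p A `state_posterior` aligned with `t` (its `index` must map
#'   frames to trials/samples, as produced via [embed_delays()]).
#' @param seg_s Segment length in seconds (default 0.5).
#' @param overlap Fractional segment overlap (default 0.5).
#' @param fmin,fmax Frequency band retained (Hz).
#' @return A `state_spectra` list: `freq` (Hz), `power` (K x channels x
#'   freqs), `coherence` (K x channels x channels x freqs), `weight`
#'   (total gamma mass per state, normalised), `channels`, `cross`
#'   (complex K x C x C x F cross-spectra), `estimator`.
#' @export
state_cross_spectra <- function(t, p, seg_s = 0.5, overlap = 0.5,
                                fmin = 1, fmax = 45) {
  stopifnot(inherits(t, "trialset"), inherits(p, "state_posterior"))
  if (is.null(p$index)) stop("posterior lacks a frame index map")
  fs <- t$fs
  nseg <- round(seg_s * fs)
  if (nseg > dim(t$data)[2]) stop("segment length exceeds trial length")
  step <- max(1L, round(nseg * (1 - overlap)))
  K <- p$K
  C <- dim(t$data)[3]
  taper <- 0.5 - 0.5 * cos(2 * pi * seq_len(nseg) / (nseg + 1))   # Hann
  u <- sum(taper^2) * fs                                           # PSD scale
  freq_all <- (seq_len(nseg) - 1) * fs / nseg
  fsel <- which(freq_all >= fmin & freq_all <= fmax & freq_all <= fs / 2)
  nf <- length(fsel)
  S <- array(0 + 0i, dim = c(K, C, C, nf))
  wtot <- numeric(K)
  n_trials <- dim(t$data)[1]
  off <- 0L
  for (i in seq_len(n_trials)) {
    Ti <- p$lengths[i]
    rows <- (off + 1L):(off + Ti)
    samp <- p$index$sample[rows]
    lo <- min(samp); hi <- max(samp)
    starts <- seq(lo, hi - nseg + 1L, by = step)
    for (s0 in starts) {
      seg <- s0:(s0 + nseg - 1L)
      g <- p$gamma[rows[match(seg, samp)], , drop = FALSE]
      w <- colMeans(g)
      x <- t$data[i, seg, , drop = FALSE]
      dim(x) <- c(nseg, C)
      x <- sweep(x, 2, colMeans(x)) * taper
      X <- stats::mvfft(x)[fsel, , drop = FALSE]
      for (k in seq_len(K)) {
        if (w[k] == 0) next
        for (f in seq_len(nf)) {
          xf <- X[f, ]
          S[k, , , f] <- S[k, , , f] + w[k] * (xf %o% Conj(xf))
        }
      }
      wtot <- wtot + w
    }
    off <- off + Ti
  }
  if (any(wtot == 0))
    warning(sprintf("state(s) %s have zero total weight; spectra undefined",
                    paste(which(wtot == 0), collapse = ", ")))
  power <- array(NA_real_, dim = c(K, C, nf))
  coh <- array(NA_real_, dim = c(K, C, C, nf))
  for (k in seq_len(K)) {
    if (wtot[k] == 0) next
    Sk <- S[k, , , , drop = FALSE] / (wtot[k] * u)
    dim(Sk) <- c(C, C, nf)
    S[k, , , ] <- Sk
    for (f in seq_len(nf)) {
      d <- Re(diag(Sk[, , f]))
      power[k, , f] <- d
      coh[k, , , f] <- Mod(Sk[, , f]) / sqrt(d %o% d)
    }
  }
  structure(list(freq = freq_all[fsel], power = power, coherence = coh,
                 weight = wtot / sum(wtot), channels = t$channels,
                 cross = S, K = K,
                 estimator = sprintf("welch hann %.3gs %.0f%% overlap",
                                     seg_s, overlap * 100)),
            class = "state_spectra")
}

#' Concatenate state coherence spectra into an NNMF feature matrix
#'
#' Stacks the upper-triangle channel-pair coherence spectra of all states
#' into a frequencies x (states * pairs) non-negative matrix, the input to
#' [nnmf_modes()].
#'
#' @param s A `state_spectra`.
#' @return Matrix with `length(s$freq)` rows; column names `state.pair`.
#' @export
coherence_features <- function(s) {
  C <- length(s$channels)
  pairs <- which(upper.tri(matrix(0, C, C)), arr.ind = TRUE)
  cols <- list(); nm <- character(0)
  for (k in seq_len(s$K)) {
    for (r in seq_len(nrow(pairs))) {
      i <- pairs[r, 1]; j <- pairs[r, 2]
      cols[[length(cols) + 1L]] <- s$coherence[k, i, j, ]
      nm <- c(nm, sprintf("s%d.%s-%s", k, s$channels[i], s$channels[j]))
    }
  }
  m <- do.call(cbind, cols)
  colnames(m) <- nm
  m
}

#' Non-negative matrix factorisation into frequency modes
#'
#' Multiplicative-update (Frobenius) NNMF of a non-negative
#' frequencies x features matrix into `n_modes` spectral profiles and their
#' loadings; the best of `n_restarts` random non-negative initialisations is
#' kept. Each mode's profile is summarised by its peak frequency and the
#' half-maximum crossing frequencies, which is how data-driven frequency
#' bands (theta, alpha, beta, gamma) are read off the factorisation.
#'
#' @param m Non-negative matrix, frequencies x features.
#' @param n_modes Number of modes (<= min(dim(m))).
#' @param freq Frequency grid (Hz) for the rows of `m`.
#' @param n_restarts Random restarts (default 10).
#' @param max_iter,tol Multiplicative-update iteration controls.
#' @param seed Integer seed.
#' @return A `frequency_modes` list: `profiles` (freqs x n_modes, each
#'   scaled to max 1), `loadings` (n_modes x features), `peak_hz`,
#'   `halfmax_hz` (n_modes x 2), `relative_error` (Frobenius), `freq`.
#' @export
nnmf_modes <- function(m, n_modes, freq = seq_len(nrow(m)), n_restarts = 10,
                       max_iter = 2000, tol = 1e-10, seed = 1L) {
  m <- as.matrix(m)
  if (any(m < 0)) stop("feature matrix must be non-negative")
  if (n_modes > min(dim(m))) stop("n_modes exceeds matrix dimensions")
  stopifnot(length(freq) == nrow(m))
  eps <- .Machine$double.eps
  best <- NULL
  for (r in seq_len(n_restarts)) {
    init <- with_seed(derive_seed(seed, paste0("nnmf_restart_", r)), {
      list(W = matrix(stats::runif(nrow(m) * n_modes, 0.1, 1), ncol = n_modes),
           H = matrix(stats::runif(n_modes * ncol(m), 0.1, 1), nrow = n_modes))
    })
    W <- init$W; H <- init$H
    err_prev <- Inf
    for (it in seq_len(max_iter)) {
      H <- H * (crossprod(W, m) / (crossprod(W) %*% H + eps))
      W <- W * (m %*% t(H) / (W %*% tcrossprod(H) + eps))
      if (it %% 10 == 0) {
        err <- sum((m - W %*% H)^2)
        if (is.finite(err_prev) && err_prev - err < tol * max(err_prev, eps)) break
        err_prev <- err
      }
    }
    err <- sqrt(sum((m - W %*% H)^2) / sum(m^2))
    if (is.null(best) || err < best$err) best <- list(W = W, H = H, err = err)
  }
  # scale profiles to unit maximum, absorb scale into loadings
  scl <- apply(best$W, 2, max)
  W <- sweep(best$W, 2, scl, "/")
  H <- sweep(best$H, 1, scl, "*")
  # order modes by peak frequency
  peak_idx <- apply(W, 2, which.max)
  ord <- order(freq[peak_idx])
  W <- W[, ord, drop = FALSE]; H <- H[ord, , drop = FALSE]
  peak_idx <- peak_idx[ord]
  halfmax <- t(vapply(seq_len(n_modes), function(k) {
    prof <- W[, k]
    above <- which(prof >= 0.5)
    c(freq[min(above)], freq[max(above)])
  }, numeric(2)))
  structure(list(profiles = W, loadings = H, peak_hz = freq[peak_idx],
                 halfmax_hz = halfmax, relative_error = best$err, freq = freq),
            class = "frequency_modes")
}

#' @export
print.frequency_modes <- function(x, ...) {
  cat(sprintf("<frequency_modes> %d modes, relative error %.3g\n",
              ncol(x$profiles), x$relative_error))
  for (k in seq_len(ncol(x$profiles)))
    cat(sprintf("  mode %d: peak %.3g Hz, half-maximum [%.3g, %.3g] Hz\n",
                k, x$peak_hz[k], x$halfmax_hz[k, 1], x$halfmax_hz[k, 2]))
  invisible(x)
}

#' Per-trial state-conditional spectral features
#'
#' For each trial and state, a gamma-weighted Welch estimate of band power
#' (per channel) and band coherence (per channel pair), aggregated over a
#' frequency band — the per-trial state-conditional estimates that
#' [state_feature_tests()] permutes.
#'
#' @param t A [trialset()].
#' @param p A `state_posterior` with an index map.
#' @param band Numeric `c(lo, hi)` in Hz.
#' @param seg_s,overlap Welch segmentation (see [state_cross_spectra()]).
#' @return List with `power` (trials x states x channels) and `coherence`
#'   (trials x states x pairs) arrays plus `pair_names`, `channels`.
#' @export
trialwise_state_features <- function(t, p, band, seg_s = 0.5, overlap = 0.5) {
  n_trials <- dim(t$data)[1]
  C <- dim(t$data)[3]
  K <- p$K
  pairs <- which(upper.tri(matrix(0, C, C)), arr.ind = TRUE)
  pw <- array(NA_real_, dim = c(n_trials, K, C))
  ch <- array(NA_real_, dim = c(n_trials, K, nrow(pairs)))
  off <- 0L
  for (i in seq_len(n_trials)) {
    Ti <- p$lengths[i]
    sub <- subset_posterior(p, (off + 1L):(off + Ti))
    ti <- trialset(t$data[i, , , drop = FALSE], t$fs, t$channels,
                   as.character(t$condition[i]), t$subject[i], t$event_sample[i])
    s <- suppressWarnings(state_cross_spectra(ti, sub, seg_s = seg_s,
                                              overlap = overlap,
                                              fmin = band[1], fmax = band[2]))
    for (k in seq_len(K)) {
      pw[i, k, ] <- rowMeans(s$power[k, , , drop = TRUE], na.rm = FALSE)
      for (r in seq_len(nrow(pairs)))
        ch[i, k, r] <- mean(s$coherence[k, pairs[r, 1], pairs[r, 2], ])
    }
    off <- off + Ti
  }
  list(power = pw, coherence = ch,
       pair_names = apply(pairs, 1, function(rr)
         paste(t$channels[rr[1]], t$channels[rr[2]], sep = "-")),
       channels = t$channels)
}

# restrict a posterior to a set of frame rows forming whole trials
subset_posterior <- function(p, rows) {
  structure(list(gamma = p$gamma[rows, , drop = FALSE],
                 viterbi = p$viterbi[rows],
                 lengths = length(rows), loglik = NA_real_, K = p$K,
                 index = p$index[rows, , drop = FALSE]),
            class = "state_posterior")
}

#' Permutation tests for state-specific spectral features
#'
#' For every feature (a trials x states matrix of state-conditional
#' estimates), compares each state's across-trial mean against a null built
#' by independently permuting the state labels within each trial, giving
#' one-tailed p-values in both directions and "higher"/"lower" flags at
#' `alpha`. Trials with missing state-conditional estimates (states never
#' visited) are dropped per feature.
#'
#' @param features Trials x states matrix, or a 3-d array trials x states x
#'   features.
#' @param n_perm Number of permutations (>= 100).
#' @param alpha Significance level (default 0.01).
#' @param seed Integer seed.
#' @return Data frame with columns feature, state, observed, p_higher,
#'   p_lower, flag.
#' @export
state_feature_tests <- function(features, n_perm = 5000, alpha = 0.01,
                                seed = 1L) {
  if (n_perm < 100) stop("n_perm must be >= 100")
  if (length(dim(features)) == 2L)
    features <- array(features, dim = c(dim(features), 1L))
  n_feat <- dim(features)[3]
  K <- dim(features)[2]
  out <- list()
  fnames <- dimnames(features)[[3]] %||% as.character(seq_len(n_feat))
  with_seed(seed, {
    for (fi in seq_len(n_feat)) {
      m <- features[, , fi]
      m <- m[stats::complete.cases(m), , drop = FALSE]
      n <- nrow(m)
      obs <- colMeans(m)
      # null: permute state labels independently within each trial
      null_means <- matrix(0, n_perm, K)
      for (b in seq_len(n_perm)) {
        perm <- m
        for (i in seq_len(n)) perm[i, ] <- m[i, sample.int(K)]
        null_means[b, ] <- colMeans(perm)
      }
      for (k in seq_len(K)) {
        p_hi <- (1 + sum(null_means[, k] >= obs[k])) / (n_perm + 1)
        p_lo <- (1 + sum(null_means[, k] <= obs[k])) / (n_perm + 1)
        flag <- if (p_hi < alpha) "higher" else if (p_lo < alpha) "lower" else "ns"
        out[[length(out) + 1L]] <- data.frame(
          feature = fnames[fi], state = k, observed = obs[k],
          p_higher = p_hi, p_lower = p_lo, flag = flag)
      }
    }
  })
  do.call(rbind, out)
}
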