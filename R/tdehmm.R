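#' Time-delay embedding of a trialset
#'
#' For a window of `L = round(window_ms * fs / 1000)` samples (odd, centred),
#' the frame at sample s of a trial stacks every channel at lags
#' `-w .. +w` (`w = (L - 1) / 2`), channel-major: all lags of channel 1,
#' then channel 2, and so on. Edge samples without a complete window are
#' dropped, so each trial contributes `n_samples - 2w` frames and no frame
#' spans a trial boundary. The sample covariance of these frames is the
#' lagged auto/cross-covariance of the channels over the window, which is
#' what the hidden states' observation model then describes.
#'
#' @param t A [trialset()].
#' @param window_ms Window length in ms; `window_ms * fs / 1000` must round
#'   to an odd integer >= 3.
#' @return An `embedded_data` list: `x` (frames x (L*C) matrix), `index`
#'   (data frame mapping each frame to its trial and centre sample),
#'   `lengths` (frames per trial), `w`, `L`, `channels`, `fs`,
#'   `lag_order = "channel-major"`.
#' @export
embed_delays <- function(t, window_ms = 60) {
  stopifnot(inherits(t, "trialset"))
  L <- round(window_ms * t$fs / 1000)
  if (L < 3 || L %% 2 == 0) stop("window must round to an odd sample count >= 3")
  w <- (L - 1L) %/% 2L
  d <- dim(t$data)
  if (d[2] <= 2L * w) stop("window longer than trial")
  n_frames_pt <- d[2] - 2L * w
  centre <- (w + 1L):(d[2] - w)
  C <- d[3]
  x <- matrix(0, d[1] * n_frames_pt, L * C)
  col <- 0L
  for (ch in seq_len(C)) {
    for (off in -w:w) {
      col <- col + 1L
      x[, col] <- as.vector(t(t$data[, centre + off, ch]))
    }
  }
  index <- data.frame(trial = rep(seq_len(d[1]), each = n_frames_pt),
                      sample = rep(centre, d[1]))
  structure(list(x = x, index = index,
                 lengths = rep(n_frames_pt, d[1]), w = w, L = L,
                 channels = t$channels, fs = t$fs,
                 lag_order = "channel-major"),
            class = "embedded_data")
}

#' Principal component analysis of embedded frames
#'
#' Eigen-decomposition of the embedded sample covariance; the top `n_pcs`
#' eigenvectors compress the `L * C`-dimensional frames before state
#' inference, which both regularises the state covariances and keeps the
#' model tractable. The recommended dimension is twice the channel count.
#'
#' @param e An `embedded_data` object.
#' @param n_pcs Number of components (<= `L * C` and <= numerical rank).
#' @return A `pca_model` list: `mean`, `loadings` (L*C x n_pcs,
#'   orthonormal), `evr` (explained-variance ratios), `eigenvalues`.
#' @export
fit_pca <- function(e, n_pcs = 16) {
  x <- e$x
  p <- ncol(x)
  if (n_pcs > p) stop("n_pcs exceeds embedding dimension")
  if (nrow(x) <= p) stop("need more frames than embedding dimensions")
  mu <- colMeans(x)
  xc <- sweep(x, 2, mu)
  cv <- crossprod(xc) / (nrow(x) - 1)
  eg <- eigen(cv, symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  rank <- sum(ev > max(ev) * 1e-12)
  if (n_pcs > rank)
    stop(sprintf("n_pcs (%d) exceeds numerical rank (%d)", n_pcs, rank))
  structure(list(mean = mu, loadings = eg$vectors[, seq_len(n_pcs), drop = FALSE],
                 evr = ev / sum(ev), eigenvalues = ev),
            class = "pca_model")
}

#' Project embedded frames onto a fitted PCA basis
#' @param pca A `pca_model`.
#' @param e An `embedded_data` (or a raw frame matrix).
#' @return Frames x n_pcs score matrix.
#' @export
project_pca <- function(pca, e) {
  x <- if (inherits(e, "embedded_data")) e$x else as.matrix(e)
  sweep(x, 2, pca$mean) %*% pca$loadings
}

# zero-mean multivariate normal log-density for all rows of x
mvn_logdens0 <- function(x, sigma) {
  d <- ncol(x)
  U <- chol(sigma)
  w <- forwardsolve(t(U), t(x))
  q <- colSums(w^2)
  -0.5 * (d * log(2 * pi) + 2 * sum(log(diag(U))) + q)
}

# regularise a covariance whose condition number exceeds cond_max
regularise_cov <- function(sigma, cond_max = 1e12) {
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0 || max(ev) / min(ev) > cond_max) {
    sigma <- sigma + diag(1e-6 * mean(diag(sigma)), nrow(sigma))
    attr(sigma, "regularised") <- TRUE
  }
  sigma
}

#' Fit a K-state hidden Markov model with zero-mean Gaussian observations
#'
#' Expectation-maximisation for an HMM whose per-state observation model is
#' a zero-mean multivariate Gaussian with full covariance — on time-delay
#' embedded (and PCA-projected) signals the state covariances are lagged
#' autocovariance patterns, i.e. oscillatory spectral signatures, rather
#' than mean levels. Trials are independent sequences: the chain restarts
#' from the initial distribution at every trial boundary and expected
#' transition counts never cross trials. The best of `n_restarts` random
#' initialisations (by final log-likelihood) is returned; ties break by
#' restart index.
#'
#' @param x Frames x d numeric matrix (already centred / PC-projected).
#' @param lengths Frames per trial, summing to `nrow(x)`.
#' @param K Number of states (>= 1).
#' @param n_restarts Random restarts (default 5).
#' @param max_iter Maximum EM iterations per restart (default 500).
#' @param tol Relative log-likelihood change declaring convergence.
#' @param seed Integer seed; restart r uses child seed `seed + r`.
#' @param verbose Print per-restart progress.
#' @return A `state_model` list: `K`, `covariances` (list of d x d),
#'   `transition` (K x K), `init`, `loglik_trace`, `loglik`, `converged`,
#'   `regularised`, `d`.
#' @export
fit_hmm <- function(x, lengths, K, n_restarts = 5, max_iter = 500,
                    tol = 1e-6, seed = 1L, verbose = FALSE) {
  x <- as.matrix(x)
  stopifnot(sum(lengths) == nrow(x), K >= 1)
  n <- nrow(x); d <- ncol(x)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    # initial responsibilities: random Dirichlet(1) draw per frame
    g <- with_seed(derive_seed(seed, paste0("hmm_restart_", r)), {
      m <- matrix(stats::rexp(n * K), n, K)
      m / rowSums(m)
    })
    A <- matrix(1 / K, K, K)
    pi0 <- rep(1 / K, K)
    covs <- mstep_covs(x, g)
    trace <- numeric(0)
    regd <- FALSE
    converged <- FALSE
    ll_prev <- -Inf
    for (it in seq_len(max_iter)) {
      logB <- matrix(0, n, K)
      for (k in seq_len(K)) logB[, k] <- mvn_logdens0(x, covs[[k]])
      fb <- fb_cpp(logB, pi0, A, as.integer(lengths))
      g <- fb$gamma
      trace <- c(trace, fb$loglik)
      if (is.finite(ll_prev) &&
          abs(fb$loglik - ll_prev) < tol * abs(ll_prev)) {
        converged <- TRUE
        break
      }
      ll_prev <- fb$loglik
      # M-step
      if (K > 1) {
        xi <- fb$xi
        A <- xi / pmax(rowSums(xi), .Machine$double.eps)
        starts <- cumsum(c(1, lengths[-length(lengths)]))
        pi0 <- colMeans(g[starts, , drop = FALSE])
        pi0 <- pi0 / sum(pi0)
      }
      covs <- mstep_covs(x, g)
      reg <- vapply(covs, function(s) isTRUE(attr(s, "regularised")), logical(1))
      if (any(reg)) regd <- TRUE
    }
    if (!converged)
      warning(sprintf("restart %d: EM did not converge within %d iterations",
                      r, max_iter))
    if (verbose)
      message(sprintf("restart %d: loglik %.2f after %d iterations",
                      r, trace[length(trace)], length(trace)))
    cand <- list(K = K, covariances = covs, transition = A, init = pi0,
                 loglik_trace = trace, loglik = trace[length(trace)],
                 converged = converged, regularised = regd, d = d,
                 restart = r)
    if (is.null(best) || cand$loglik > best$loglik) best <- cand
  }
  structure(best, class = "state_model")
}

# weighted zero-mean covariance per state, with collapse regularisation
mstep_covs <- function(x, g) {
  lapply(seq_len(ncol(g)), function(k) {
    wk <- g[, k]
    s <- crossprod(x * sqrt(wk)) / pmax(sum(wk), .Machine$double.eps)
    regularise_cov(s)
  })
}

#' @export
print.state_model <- function(x, ...) {
  cat(sprintf("<state_model> K = %d, dim = %d, loglik = %.2f (%s, %d iterations)\n",
              x$K, x$d, x$loglik,
              if (x$converged) "converged" else "NOT converged",
              length(x$loglik_trace)))
  invisible(x)
}

#' Decode state posteriors and the Viterbi path
#'
#' Forward-backward marginal state probabilities (gamma) and the single
#' most probable state path (Viterbi), computed independently per trial.
#'
#' @param m A `state_model`.
#' @param x Frames x d matrix in the model's observation space.
#' @param lengths Frames per trial.
#' @param index Optional frame index map (as from [embed_delays()]).
#' @return A `state_posterior` list: `gamma` (frames x K, rows sum to 1),
#'   `viterbi` (integer frames vector), `lengths`, `loglik`, `index`.
#' @export
decode_states <- function(m, x, lengths, index = NULL) {
  x <- as.matrix(x)
  if (ncol(x) != m$d) stop("data dimension does not match model")
  stopifnot(sum(lengths) == nrow(x))
  n <- nrow(x); K <- m$K
  logB <- matrix(0, n, K)
  for (k in seq_len(K)) logB[, k] <- mvn_logdens0(x, m$covariances[[k]])
  fb <- fb_cpp(logB, m$init, m$transition, as.integer(lengths))
  logA <- log(pmax(m$transition, 1e-300))
  logpi <- log(pmax(m$init, 1e-300))
  vit <- viterbi_cpp(logB, logpi, logA, as.integer(lengths))
  structure(list(gamma = fb$gamma, viterbi = as.integer(vit),
                 lengths = as.integer(lengths), loglik = fb$loglik,
                 K = K, index = index),
            class = "state_posterior")
}

#' State dynamics metrics: occupancy, lifetimes, switching rate
#'
#' From the per-trial Viterbi path: fractional occupancy (FO) is the
#' fraction of a trial's frames assigned to each state; a lifetime is the
#' duration of one maximal uninterrupted dwell in a state (seconds); the
#' switching rate (SR) is the number of state changes divided by the trial
#' duration in seconds. Hard Viterbi assignments are used so that FO and
#' the lifetimes are mutually consistent (their per-state sums agree to
#' one sample).
#'
#' @param p A `state_posterior`.
#' @param fs Sampling rate (Hz) used to convert frames to seconds.
#' @return A `state_metrics` list: `fo` (trials x K), `sr` (per trial,
#'   switches/s), `lifetimes` (list over trials of lists over states of
#'   dwell durations in s), `duration` (trial duration, s), `K`, `fs`.
#' @export
state_metrics <- function(p, fs) {
  stopifnot(inherits(p, "state_posterior"))
  K <- p$K
  n_trials <- length(p$lengths)
  fo <- matrix(0, n_trials, K)
  sr <- numeric(n_trials)
  lifetimes <- vector("list", n_trials)
  off <- 0L
  for (i in seq_len(n_trials)) {
    Ti <- p$lengths[i]
    if (Ti == 0L) stop("empty trial")
    path <- p$viterbi[(off + 1L):(off + Ti)]
    fo[i, ] <- tabulate(path, K) / Ti
    sr[i] <- sum(diff(path) != 0L) / (Ti / fs)
    runs <- rle(path)
    lt <- vector("list", K)
    for (k in seq_len(K)) lt[[k]] <- runs$lengths[runs$values == k] / fs
    lifetimes[[i]] <- lt
    off <- off + Ti
  }
  structure(list(fo = fo, sr = sr, lifetimes = lifetimes,
                 duration = p$lengths / fs, K = K, fs = fs),
            class = "state_metrics")
}

#' Optimal state relabelling against a reference path
#'
#' Finds the state permutation maximising frame-wise agreement between a
#' decoded path and a reference (ground-truth) path, and reports the
#' matched accuracy — the standard way to score state recovery, since
#' state labels are arbitrary up to permutation.
#'
#' @param decoded,reference Integer paths of equal length over 1..K.
#' @param K Number of states.
#' @return List: `permutation` (decoded label -> reference label),
#'   `accuracy` (fraction of frames agreeing after relabelling).
#' @export
match_paths <- function(decoded, reference, K = max(reference)) {
  stopifnot(length(decoded) == length(reference))
  conf <- matrix(0, K, K)
  for (k in seq_len(K))
    conf[k, ] <- tabulate(reference[decoded == k], K)
  perms <- all_permutations(K)
  scores <- vapply(seq_len(nrow(perms)), function(i)
    sum(conf[cbind(seq_len(K), perms[i, ])]), numeric(1))
  best <- perms[which.max(scores), ]
  list(permutation = best, accuracy = max(scores) / length(decoded))
}

# all permutations of 1..K as rows (K small)
all_permutations <- function(K) {
  if (K == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(K - 1L)
  out <- NULL
  for (pos in seq_len(K)) {
    m <- cbind(sub, K)
    if (pos < K) m <- m[, append(seq_len(K - 1L), K, after = pos - 1L), drop = FALSE]
    out <- rbind(out, m)
  }
  dimnames(out) <- NULL
  out
}
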