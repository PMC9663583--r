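# Independent brute-force HMM oracle: exhaustive enumeration over all K^T
# state paths, computed entirely in R with direct density arithmetic. Used
# to validate the package's forward-backward and Viterbi implementations.

# log N(x; 0, sigma) for one observation vector
oracle_logdens <- function(x, sigma) {
  d <- length(x)
  -0.5 * (d * log(2 * pi) + determinant(sigma, logarithm = TRUE)$modulus +
            drop(x %*% solve(sigma) %*% x))
}

# enumerate all paths; return gamma (T x K), viterbi path, loglik
oracle_hmm <- function(x, covs, pi0, A) {
  T_ <- nrow(x); K <- length(covs)
  logB <- sapply(seq_len(K), function(k)
    apply(x, 1, oracle_logdens, sigma = covs[[k]]))
  if (T_ == 1L) logB <- matrix(logB, nrow = 1)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), T_)))
  logp <- apply(paths, 1, function(s) {
    lp <- log(pi0[s[1]]) + logB[1, s[1]]
    if (T_ > 1) for (t in 2:T_)
      lp <- lp + log(A[s[t - 1], s[t]]) + logB[t, s[t]]
    lp
  })
  m <- max(logp)
  w <- exp(logp - m)
  loglik <- m + log(sum(w))
  gamma <- matrix(0, T_, K)
  for (t in seq_len(T_)) for (k in seq_len(K))
    gamma[t, k] <- sum(w[paths[, t] == k]) / sum(w)
  list(gamma = gamma, viterbi = paths[which.max(logp), ], loglik = loglik)
}

# random positive-definite covariance
rand_cov <- function(d, scale = 1) {
  a <- matrix(rnorm(d * d), d)
  crossprod(a) / d * scale + diag(0.1, d)
}

# random stochastic matrix
rand_stoch <- function(K) {
  a <- matrix(rexp(K * K), K)
  a / rowSums(a)
}

# small trialset of white noise for container tests
noise_trialset <- function(n_trials = 2, n_samples = 275, channels = default_channels(),
                           fs = 250, seed = 1) {
  set.seed(seed)
  arr <- array(rnorm(n_trials * n_samples * length(channels)),
               dim = c(n_trials, n_samples, length(channels)))
  trialset(arr, fs = fs, channels = channels,
           condition = rep_len(condition_levels(), n_trials),
           subject = sprintf("S%02d", rep_len(1:4, n_trials)),
           event_sample = max(1L, n_samples - round(0.1 * fs)))
}

# state posterior constructed from ground-truth paths (one-hot gamma),
# aligned with the frames an embedding with half-window w would keep
truth_posterior <- function(paths, w, K = max(paths)) {
  n_trials <- nrow(paths); n_samples <- ncol(paths)
  centre <- (w + 1L):(n_samples - w)
  vit <- as.vector(t(paths[, centre, drop = FALSE]))
  gamma <- matrix(0, length(vit), K)
  gamma[cbind(seq_along(vit), vit)] <- 1
  structure(list(gamma = gamma, viterbi = vit,
                 lengths = rep(length(centre), n_trials), loglik = NA_real_,
                 K = K,
                 index = data.frame(trial = rep(seq_len(n_trials),
                                                each = length(centre)),
                                    sample = rep(centre, n_trials))),
            class = "state_posterior")
}
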