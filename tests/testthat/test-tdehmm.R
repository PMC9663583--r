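test_that("time-delay embedding has the stated geometry", {
  ts <- noise_trialset(3, 275)
  e <- embed_delays(ts, 60)
  expect_equal(e$L, 15)
  expect_equal(ncol(e$x), 15 * 8)
  expect_equal(e$lengths, rep(275 - 14, 3))      # 261 valid frames per trial
  expect_equal(nrow(e$x), 3 * 261)
  expect_false(any(e$index$sample < 8 | e$index$sample > 268))

  # frame content: channel-major lags -w..+w around the centre sample
  i <- 500
  tr <- e$index$trial[i]; s <- e$index$sample[i]
  expect_equal(e$x[i, ], as.vector(sapply(1:8, function(c0)
    ts$data[tr, (s - 7):(s + 7), c0])))

  # constant input: all rows identical
  tc <- ts; tc$data[] <- 2
  ec <- embed_delays(tc, 60)
  expect_equal(max(abs(sweep(ec$x, 2, ec$x[1, ]))), 0)

  expect_error(embed_delays(ts, 64), "odd")
  short <- noise_trialset(2, 10)
  expect_error(embed_delays(short, 100), "longer than trial")
})

test_that("embedded white noise has near-diagonal covariance", {
  ts <- noise_trialset(400, 275, channels = c("a", "b"), seed = 6)
  e <- embed_delays(ts, 60)   # > 1e5 frames
  cv <- cor(e$x)
  off <- abs(cv[upper.tri(cv)])
  expect_lt(max(off), 0.05)
})

test_that("PCA matches an independent eigen-decomposition and conserves variance", {
  ts <- noise_trialset(6, 120, channels = letters[1:3], seed = 9)
  e <- embed_delays(ts, 60)
  p_full <- fit_pca(e, n_pcs = ncol(e$x))
  expect_equal(sum(p_full$evr), 1, tolerance = 1e-8)
  expect_equal(crossprod(p_full$loadings), diag(ncol(e$x)), tolerance = 1e-8,
               ignore_attr = TRUE)

  # oracle: brute-force covariance eigenvectors span the same subspace
  xc <- sweep(e$x, 2, colMeans(e$x))
  ev <- eigen(crossprod(xc) / (nrow(xc) - 1), symmetric = TRUE)
  p8 <- fit_pca(e, 8)
  expect_equal(abs(diag(crossprod(p8$loadings, ev$vectors[, 1:8]))),
               rep(1, 8), tolerance = 1e-6)
  expect_equal(p8$evr[1:8], ev$values[1:8] / sum(ev$values), tolerance = 1e-8)

  # exactly 3-dimensional data reconstructs perfectly from 3 components
  set.seed(10)
  basis <- qr.Q(qr(matrix(rnorm(45 * 3), 45, 3)))
  scores3 <- matrix(rnorm(600 * 3), 600, 3) %*% t(basis)
  e3 <- list(x = scores3)
  class(e3) <- "embedded_data"
  p3 <- fit_pca(e3, 3)
  rec <- project_pca(p3, e3) %*% t(p3$loadings)
  rec <- sweep(rec, 2, -p3$mean)
  expect_lt(max(abs(rec - scores3)), 1e-8)
  expect_error(fit_pca(e3, 4), "rank")
})

test_that("forward-backward and Viterbi agree with exhaustive enumeration", {
  set.seed(41)
  for (case in 1:60) {
    K <- sample(2:3, 1)
    T_ <- sample(2:6, 1)
    d <- sample(1:2, 1)
    covs <- replicate(K, rand_cov(d), simplify = FALSE)
    A <- rand_stoch(K)
    pi0 <- as.vector(rand_stoch(K)[1, ])
    x <- matrix(rnorm(T_ * d), T_, d)
    m <- structure(list(K = K, covariances = covs, transition = A, init = pi0,
                        d = d), class = "state_model")
    got <- decode_states(m, x, T_)
    want <- oracle_hmm(x, covs, pi0, A)
    expect_equal(got$gamma, want$gamma, tolerance = 1e-8)
    expect_equal(got$viterbi, unname(want$viterbi))
    expect_equal(got$loglik, want$loglik, tolerance = 1e-8)
  }
})

test_that("gamma rows always sum to one and doomed states get zero mass", {
  set.seed(42)
  x <- matrix(rnorm(40), 20, 2)
  covs <- list(diag(2), diag(2) * 1e-8)  # state 2 likelihood ~ 0 off-origin
  m <- structure(list(K = 2, covariances = covs,
                      transition = matrix(0.5, 2, 2), init = c(0.5, 0.5),
                      d = 2), class = "state_model")
  p <- decode_states(m, x, c(12, 8))
  expect_lt(max(abs(rowSums(p$gamma) - 1)), 1e-10)
  expect_lt(max(p$gamma[, 2]), 1e-6)
})

test_that("EM recovers a planted 2-state model and increases its objective", {
  set.seed(43)
  A <- matrix(c(0.95, 0.05, 0.1, 0.9), 2, byrow = TRUE)
  covs <- list(diag(2), matrix(c(6, 2.5, 2.5, 3), 2))
  n <- 50000
  states <- integer(n); states[1] <- 1
  for (t in 2:n) states[t] <- sample.int(2, 1, prob = A[states[t - 1], ])
  x <- t(sapply(states, function(s)
    drop(t(chol(covs[[s]])) %*% rnorm(2))))
  fit <- fit_hmm(x, lengths = n, K = 2, n_restarts = 2, max_iter = 100,
                 seed = 3)
  # objective trace is monotone non-decreasing (EM guarantee)
  expect_true(all(diff(fit$loglik_trace) >= -1e-8 * abs(fit$loglik)))
  # transition entries recovered within 0.05 after label matching
  perm <- if (sum(diag(fit$covariances[[1]])) <
              sum(diag(fit$covariances[[2]]))) 1:2 else 2:1
  Ahat <- fit$transition[perm, perm]
  expect_lt(max(abs(Ahat - A)), 0.05)
  covhat <- fit$covariances[perm]
  expect_lt(max(abs(covhat[[1]] - covs[[1]])), 0.3)
  expect_lt(max(abs(covhat[[2]] - covs[[2]])), 0.3)
})

test_that("K = 1 degenerates to a single zero-mean Gaussian fit", {
  set.seed(44)
  x <- matrix(rnorm(600), 300, 2)
  fit <- fit_hmm(x, lengths = c(150, 150), K = 1, n_restarts = 1, seed = 1)
  p <- decode_states(fit, x, c(150, 150))
  expect_true(all(p$gamma == 1))
  # objective equals the single-Gaussian log-likelihood at the MLE covariance
  s <- crossprod(x) / nrow(x)
  ll <- sum(mvtnorm_logd <- apply(x, 1, function(r)
    -0.5 * (2 * log(2 * pi) + determinant(s)$modulus + r %*% solve(s) %*% r)))
  expect_equal(fit$loglik, ll, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("state metrics are consistent hand-computable summaries", {
  p <- structure(list(gamma = NULL, viterbi = c(1L, 1L, 2L, 2L, 2L),
                      lengths = 5L, K = 2, index = NULL),
                 class = "state_posterior")
  m <- state_metrics(p, fs = 250)
  expect_equal(m$fo[1, ], c(0.4, 0.6))
  expect_equal(m$sr[1], 1 / (5 / 250))          # one switch over 20 ms
  expect_equal(m$lifetimes[[1]][[1]], 2 / 250)  # 8 ms dwell in state 1

  # constant path: SR 0, one-hot FO, single lifetime = trial length
  pc <- structure(list(viterbi = rep(2L, 10), lengths = 10L, K = 3),
                  class = "state_posterior")
  mc <- state_metrics(pc, fs = 100)
  expect_equal(mc$sr[1], 0)
  expect_equal(mc$fo[1, ], c(0, 1, 0))
  expect_equal(mc$lifetimes[[1]][[2]], 0.1)

  # random paths: lifetimes per state sum to FO x duration exactly
  set.seed(45)
  vit <- sample.int(3, 400, replace = TRUE)
  pr <- structure(list(viterbi = vit, lengths = c(250L, 150L), K = 3),
                  class = "state_posterior")
  mr <- state_metrics(pr, fs = 250)
  for (i in 1:2) for (k in 1:3)
    expect_equal(sum(mr$lifetimes[[i]][[k]]), mr$fo[i, k] * mr$duration[i],
                 tolerance = 1e-12)
})

test_that("relabelling generator states only permutes the decoded labels", {
  sim <- simulate_study(n_trials = 60, n_subjects = 6, seed = 51)
  perm <- c(3L, 1L, 4L, 2L)
  spec_p <- sim$truth$spec
  spec_p$states <- spec_p$states[order(perm)]
  paths_p <- sim$truth$paths
  paths_p$paths[] <- perm[sim$truth$paths$paths]
  ts_p <- synthesize_signals(paths_p, spec_p, fs = 250,
                             condition = as.character(sim$trials$condition),
                             subject = sim$trials$subject,
                             seed = derive_seed(51, "signals"))
  cfg <- pipeline_config()
  w <- 7
  # after optimal matching against the truth, decoded occupancies agree
  # with the true ones under either labelling of the generator
  for (run in 1:2) {
    trials <- if (run == 1) sim$trials else ts_p
    truth <- if (run == 1) sim$truth$paths$paths else paths_p$paths
    f <- fit_state_pipeline(trials, cfg, n_restarts = 3, max_iter = 150,
                            seed = 5)
    tf <- as.vector(t(truth[, (w + 1):(275 - w)]))
    m <- match_paths(f$posterior$viterbi, tf, K = 4)
    expect_gt(m$accuracy, 0.8)
    fo_dec <- colMeans(f$metrics$fo)[order(m$permutation)]
    fo_true <- tabulate(tf, 4) / length(tf)
    # per-state occupancy error is bounded by the frame misclassification rate
    expect_lte(max(abs(fo_dec - fo_true)), 1 - m$accuracy + 1e-12)
  }
})
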