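test_that("coherence is exact for shared oscillators and bounded in [0,1]", {
  # two channels sharing one oscillator, no noise: coherence 1 at its bin
  spec <- state_spec(list(list(list(
    freq = 12, amp = c(1, 1),
    couple = list(list(channels = c("a", "b"), lags = c(0, pi / 3),
                       strength = 1))))),
    noise_sd = 0, pink_sd = 0, channels = c("a", "b"))
  paths <- matrix(1L, 10, 275)
  ts <- synthesize_signals(paths, spec, fs = 250, seed = 12)
  post <- truth_posterior(paths, w = 7, K = 1)
  s <- state_cross_spectra(ts, post)
  bin <- which.min(abs(s$freq - 12))
  expect_equal(s$coherence[1, 1, 2, bin], 1, tolerance = 1e-6)
  expect_true(all(s$coherence >= 0 & s$coherence <= 1 + 1e-12, na.rm = TRUE))
  expect_equal(s$coherence[1, 1, 1, ], rep(1, length(s$freq)),
               tolerance = 1e-8)

  # independent white noise: low coherence floor
  tn <- noise_trialset(200, 275, channels = c("a", "b"), seed = 13)
  pn <- truth_posterior(matrix(1L, 200, 275), w = 7, K = 1)
  sn <- state_cross_spectra(tn, pn)
  expect_lt(quantile(sn$coherence[1, 1, 2, ], 0.95), 0.3)
})

test_that("planted state-specific coupling shows up only in that state", {
  sim <- simulate_study(n_trials = 120, n_subjects = 8, gc_gain = 0, seed = 14)
  post <- truth_posterior(sim$truth$paths$paths, w = 7, K = 4)
  s <- state_cross_spectra(sim$trials, post)
  i <- match(c("PCU", "V1"), sim$trials$channels)
  bin <- which.min(abs(s$freq - 11))
  coh <- s$coherence[, i[1], i[2], bin]
  expect_equal(which.max(coh), 4)              # state 4 carries the coupling
  expect_gt(coh[4], max(coh[-4]) + 0.2)
})

test_that("gamma-weighted state spectra average back to the unconditional one", {
  set.seed(15)
  tn <- noise_trialset(6, 275, seed = 15)
  n_frames <- 261
  gamma <- matrix(rexp(6 * n_frames * 3), ncol = 3)
  gamma <- gamma / rowSums(gamma)
  post <- truth_posterior(matrix(1L, 6, 275), w = 7, K = 1)
  post3 <- post; post3$gamma <- gamma; post3$K <- 3
  post3$viterbi <- max.col(gamma)
  s3 <- state_cross_spectra(tn, post3)
  s1 <- state_cross_spectra(tn, post)
  mix <- array(0 + 0i, dim = dim(s3$cross)[2:4])
  for (k in 1:3) mix <- mix + s3$weight[k] * s3$cross[k, , , ]
  expect_equal(mix, s1$cross[1, , , ], tolerance = 1e-8)
})

test_that("NNMF recovers planted spectral modes", {
  freq <- 1:45
  bump <- function(mu, sig) exp(-(freq - mu)^2 / (2 * sig^2))
  # exact rank-1: single 11 Hz bump
  set.seed(16)
  m1 <- bump(11, 2) %o% runif(30, 0.5, 2)
  f1 <- nnmf_modes(m1, 1, freq = freq, seed = 2)
  expect_equal(f1$peak_hz, 11)
  expect_lt(f1$relative_error, 1e-3)

  # exact low-rank matrix factorises to numerical precision
  W <- cbind(bump(4, 2), bump(11, 2), bump(20, 3))
  H <- matrix(runif(3 * 40, 0.2, 1.5), 3)
  f3 <- nnmf_modes(W %*% H, 3, freq = freq, seed = 3)
  expect_lt(f3$relative_error, 1e-5)
  expect_equal(f3$peak_hz, c(4, 11, 20), tolerance = 1)
  # half-maximum bounds bracket each peak
  expect_true(all(f3$halfmax_hz[, 1] <= f3$peak_hz &
                  f3$peak_hz <= f3$halfmax_hz[, 2]))

  # reconstruction error is monotone non-increasing in the mode count
  set.seed(17)
  noisy <- W %*% H + matrix(runif(45 * 40, 0, 0.05), 45)
  errs <- sapply(1:6, function(r)
    nnmf_modes(noisy, r, freq = freq, n_restarts = 4, seed = 4)$relative_error)
  expect_true(all(diff(errs) <= 1e-6))

  expect_error(nnmf_modes(matrix(c(-1, 1, 1, 1), 2), 1), "non-negative")
  expect_error(nnmf_modes(matrix(1, 4, 4), 5), "exceeds")
})

test_that("state feature tests flag planted margins and stay calibrated", {
  set.seed(18)
  # planted: state 3 higher by 0.4 on feature 1
  n <- 40
  feats <- array(rnorm(n * 4 * 2, mean = 0.3, sd = 0.1), dim = c(n, 4, 2))
  feats[, 3, 1] <- feats[, 3, 1] + 0.4
  res <- state_feature_tests(feats, n_perm = 1000, alpha = 0.01, seed = 7)
  hit <- res[res$feature == "1" & res$state == 3, ]
  expect_equal(hit$flag, "higher")
  expect_lte(hit$p_higher, 0.01)
  expect_true(all(res$p_higher >= 1 / 1001 & res$p_lower >= 1 / 1001))

  # exchangeable states: false-positive rate near alpha
  fp <- mean(replicate(60, {
    f0 <- array(rnorm(20 * 4), dim = c(20, 4, 1))
    r0 <- state_feature_tests(f0, n_perm = 200, alpha = 0.05, seed = sample.int(1e6, 1))
    mean(r0$flag != "ns")
  }))
  # two one-tailed tests at alpha each => per-state rate <= ~2 alpha
  expect_lt(fp, 2 * 0.05 + 2 * sqrt(0.1 * 0.9 / (60 * 4)))
  expect_error(state_feature_tests(feats, n_perm = 50), "100")
})
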