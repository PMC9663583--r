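test_that("state paths honour the transition structure", {
  # identity transitions freeze every chain at its initial state
  p <- sample_state_paths(diag(4), rep(0.25, 4), 50, 30, seed = 2)
  expect_true(all(apply(p$paths, 1, function(r) length(unique(r)) == 1)))

  # K = 1 gives all-ones paths
  p1 <- sample_state_paths(matrix(1, 1, 1), 1, 5, 10, seed = 1)
  expect_true(all(p1$paths == 1L))

  expect_error(sample_state_paths(matrix(c(0.5, 0.2, 0.5, 0.5), 2), c(1, 0),
                                  2, 5), "sum to 1")
})

test_that("dwell lengths match the geometric expectation", {
  A <- matrix(0.02 / 3, 4, 4); diag(A) <- 0.98
  # long chains so that completed dwells are essentially uncensored
  p <- sample_state_paths(A, rep(0.25, 4), 150, 10000, seed = 5)
  dwells <- unlist(apply(p$paths, 1, function(r) {
    runs <- rle(r)$lengths
    # drop the right-censored last run of each trial
    if (length(runs) > 1) runs[-length(runs)] else numeric(0)
  }))
  expect_equal(mean(dwells), 50, tolerance = 0.05)  # 1 / (1 - 0.98)
})

test_that("occupancy converges to the chain's stationary distribution", {
  A <- rand_stoch(4)
  stationary <- Re(eigen(t(A))$vectors[, 1])
  stationary <- stationary / sum(stationary)
  p <- sample_state_paths(A, stationary, 5000, 100, seed = 7)
  occ <- tabulate(p$paths, 4) / length(p$paths)
  expect_lt(max(abs(occ - stationary)), 0.02)
})

test_that("a single noiseless component is a pure sinusoid at its frequency", {
  spec <- state_spec(list(list(list(freq = 11, amp = 1))),
                     noise_sd = 0, pink_sd = 0, channels = "c1")
  paths <- matrix(1L, 1, 500)
  ts <- synthesize_signals(paths, spec, fs = 250, seed = 3)
  x <- ts$data[1, , 1]
  expect_equal(max(abs(x)), 1, tolerance = 1e-6)
  pg <- Mod(fft(x))[1:250]
  peak_hz <- (which.max(pg) - 1) * 250 / 500
  expect_equal(peak_hz, 11)
})

test_that("planted phase coupling appears (only) as spectral coherence", {
  spec <- state_spec(list(list(list(
    freq = 11, amp = rep(1, 8),
    couple = list(list(channels = c("PCU", "V1"), lags = c(0, 0),
                       strength = 1))))),
    noise_sd = 0.2, pink_sd = 0, channels = default_channels())
  paths <- matrix(1L, 100, 275)
  ts <- synthesize_signals(paths, spec, fs = 250, seed = 4)
  post <- truth_posterior(paths, w = 7, K = 1)
  s <- state_cross_spectra(ts, post)
  i <- match(c("PCU", "V1"), ts$channels)
  bin <- which.min(abs(s$freq - 11))
  expect_gt(s$coherence[1, i[1], i[2], bin], 0.95)

  # strength 0: coherence indistinguishable from independent-noise channels
  spec0 <- spec; spec0$states[[1]][[1]]$couple[[1]]$strength <- 0
  ts0 <- synthesize_signals(paths, spec0, fs = 250, seed = 4)
  s0 <- state_cross_spectra(ts0, post)
  # lHP/rHP are independent pure-noise references in both runs
  noise_floor <- s0$coherence[1, 1, 2, bin]
  expect_lt(s0$coherence[1, i[1], i[2], bin], noise_floor + 0.15)
})

test_that("lagged coupling injection is gated and recoverable", {
  ts <- noise_trialset(20, 275)
  # gain 0 leaves the data untouched
  expect_identical(inject_lagged_coupling(ts, "PCU", "V1", 2, 0)$data, ts$data)
  expect_error(inject_lagged_coupling(ts, "V1", "V1", 2, 1), "differ")

  t2 <- inject_lagged_coupling(ts, "PCU", "V1", lag = 2, gain = 0.5)
  is_ <- match("PCU", ts$channels); id <- match("V1", ts$channels)
  expect_identical(t2$data[, , is_], ts$data[, , is_])  # source unchanged
  cc <- ccf(as.vector(t(t2$data[, , id])), as.vector(t(t2$data[, , is_])),
            lag.max = 10, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 2)

  # gated injection: regression on non-gated frames recovers ~0 gain
  paths <- matrix(rep(c(1L, 2L), each = 10), 20, 275)
  t3 <- inject_lagged_coupling(ts, "PCU", "V1", lag = 2, gain = 0.5,
                               gate = 2L, paths = paths)
  gated <- paths[, 3:275] == 2L
  y <- t3$data[, 3:275, id] - ts$data[, 3:275, id]
  x <- t3$data[, 1:273, is_]
  fit_on <- coef(lm(as.vector(y[gated]) ~ as.vector(x[gated])))[2]
  expect_equal(unname(fit_on), 0.5, tolerance = 1e-8)
  expect_equal(sum(abs(y[!gated])), 0)
})

test_that("behavioural durations follow the gamma interaction GLM", {
  # null slopes: mean equals exp(b0) within Monte-Carlo error
  b <- sample_behavior(runif(10000), rnorm(10000), coef = c(0.5, 0, 0, 0),
                       shape = 2, seed = 8)
  se <- sd(b$duration) / sqrt(nrow(b))
  expect_lt(abs(mean(b$duration) - exp(0.5)), 3 * se)

  # negative interaction: gc and duration anticorrelate at high lifetime
  b2 <- sample_behavior(rep(1, 5000), rnorm(5000), coef = c(0.5, 0, 0, -0.4),
                        shape = 2, seed = 9)
  expect_lt(cor(b2$gc, b2$duration), 0)

  # gamma identity: variance / mean^2 -> 1 / shape
  b3 <- sample_behavior(rep(0, 20000), rep(0, 20000), coef = c(0.3, 0, 0, 0),
                        shape = 100, seed = 10)
  expect_equal(var(b3$duration) / mean(b3$duration)^2, 1 / 100,
               tolerance = 0.05)
  expect_error(sample_behavior(1, 1, shape = 0), "shape")
})

test_that("the study generator is reproducible and condition-biased", {
  s1 <- simulate_study(n_trials = 40, seed = 21)
  s2 <- simulate_study(n_trials = 40, seed = 21)
  expect_identical(s1$trials$data, s2$trials$data)
  expect_identical(s1$behavior$duration, s2$behavior$duration)

  # per-condition trial counts follow the study proportions
  counts <- table(s1$trials$condition)
  expect_equal(sum(counts), 40)
  expect_equal(unname(counts["BR_dom"] >= counts["RPL_mix"]), TRUE)

  # each condition's indicative state is its most-occupied state
  K <- 4
  fo <- t(apply(s1$truth$paths$paths, 1, function(r) tabulate(r, K) / length(r)))
  for (cd in condition_levels()) {
    sel <- s1$trials$condition == cd
    expect_equal(which.max(colMeans(fo[sel, , drop = FALSE])),
                 unname(s1$truth$indicative[cd]))
  }
})
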