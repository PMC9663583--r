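#' Epoch trials to a window and apply baseline correction
#'
#' Crops every trial to `window` (seconds relative to the response event)
#' and subtracts, per trial and channel, the mean over the `baseline`
#' interval, so slow offsets present before the window of interest are
#' removed from the whole epoch.
#'
#' @param t A [trialset()].
#' @param window Numeric `c(start, end)` in seconds relative to the event.
#' @param baseline Numeric `c(b0, b1)` in seconds; must lie within `window`.
#' @return A baseline-corrected `trialset` restricted to `window`.
#' @export
epoch_and_baseline <- function(t, window, baseline) {
  stopifnot(inherits(t, "trialset"), length(window) == 2L, length(baseline) == 2L)
  if (baseline[1] < window[1] || baseline[2] > window[2])
    stop("baseline interval must lie within the epoch window")
  n_samples <- dim(t$data)[2]
  n_trials <- dim(t$data)[1]
  out <- NULL
  for (i in seq_len(n_trials)) {
    ev <- t$event_sample[i]
    idx <- (ev + round(window[1] * t$fs)):(ev + round(window[2] * t$fs))
    if (idx[1] < 1L || idx[length(idx)] > n_samples)
      stop("epoch window outside recorded samples")
    bidx <- (ev + round(baseline[1] * t$fs)):(ev + round(baseline[2] * t$fs))
    x <- t$data[i, idx, , drop = FALSE]
    dim(x) <- dim(x)[2:3]
    b <- t$data[i, bidx, , drop = FALSE]
    dim(b) <- dim(b)[2:3]
    x <- sweep(x, 2, colMeans(b))
    if (is.null(out)) out <- array(0, dim = c(n_trials, length(idx), dim(t$data)[3]))
    out[i, , ] <- x
  }
  trialset(out, fs = t$fs, channels = t$channels, condition = t$condition,
           subject = t$subject,
           event_sample = 1L - round(window[1] * t$fs),
           meta = c(t$meta, list(epoch_window_s = window, baseline_s = baseline)))
}

#' Global field power of condition-averaged evoked responses
#'
#' Averages epochs across trials within each condition (the evoked
#' response) and returns, at each time point, the standard deviation of
#' that average across channels — computed with the population formula
#' (divide by the channel count), the convention under which two channels
#' at +1 and -1 give a GFP of exactly 1.
#'
#' @param t An epoched [trialset()] with at least two channels.
#' @param by Grouping of trials: `"condition"` (default) or a factor of
#'   length `n_trials`.
#' @return An `evoked_series` list: `time` (s, relative to event), `evoked`
#'   (named list of time x channel matrices), `gfp` (time x group matrix).
#' @export
global_field_power <- function(t, by = "condition") {
  stopifnot(inherits(t, "trialset"))
  if (dim(t$data)[3] < 2L) stop("GFP requires at least 2 channels")
  groups <- if (identical(by, "condition")) t$condition else factor(by)
  time <- trial_times(t)
  evoked <- list(); gfp <- NULL
  for (g in levels(groups)) {
    sel <- which(groups == g)
    avg <- apply(t$data[sel, , , drop = FALSE], c(2, 3), mean)
    evoked[[g]] <- avg
    gfp <- cbind(gfp, apply(avg, 1, pop_sd))
  }
  colnames(gfp) <- levels(groups)
  structure(list(time = time, evoked = evoked, gfp = gfp),
            class = "evoked_series")
}

#' One-dimensional cluster-based permutation test
#'
#' One-sample t-test of per-subject difference series at each time point;
#' contiguous runs of same-signed supra-threshold t-values form clusters
#' scored by their summed t (cluster mass). The null distribution of the
#' maximum absolute cluster mass is built by randomly sign-flipping whole
#' subject series, giving family-wise corrected p-values over the window.
#'
#' @param diffs Subjects x timepoints matrix of paired differences.
#' @param n_perm Number of sign-flip permutations (>= 100).
#' @param cluster_threshold Cluster-forming |t| threshold; default is the
#'   two-tailed 0.05 critical value with `nrow(diffs) - 1` df.
#' @param alpha Significance level for flagging clusters.
#' @param time Optional time axis (s) for reporting cluster extents;
#'   defaults to sample indices.
#' @param seed Integer seed for the permutations.
#' @return A `cluster_test` list: `clusters` data frame (start, end, mass,
#'   p, significant), `threshold`, `n_perm`, `t` (observed t series).
#' @export
cluster_permutation_test <- function(diffs, n_perm = 1000,
                                     cluster_threshold = NULL, alpha = 0.05,
                                     time = NULL, seed = 1L) {
  diffs <- as.matrix(diffs)
  n_sub <- nrow(diffs); n_time <- ncol(diffs)
  if (n_sub < 2) stop("at least 2 subjects required")
  if (n_perm < 100) stop("n_perm must be >= 100")
  time <- time %||% seq_len(n_time)
  sds <- apply(diffs, 2, stats::sd)
  keep <- sds > 0
  if (!all(keep)) {
    warning(sprintf("%d zero-variance time point(s) excluded", sum(!keep)))
  }
  thr <- cluster_threshold %||% stats::qt(0.975, df = n_sub - 1)

  tser <- function(x) {
    m <- colMeans(x); s <- apply(x, 2, stats::sd)
    tt <- rep(0, length(m))
    tt[keep] <- m[keep] / (s[keep] / sqrt(nrow(x)))
    tt
  }
  # clusters of contiguous same-signed supra-threshold points
  cluster_masses <- function(tt) {
    lab <- sign(tt) * (abs(tt) > thr)
    res <- list()
    i <- 1L
    while (i <= length(lab)) {
      if (lab[i] != 0) {
        j <- i
        while (j < length(lab) && lab[j + 1L] == lab[i]) j <- j + 1L
        res[[length(res) + 1L]] <- c(start = i, end = j, mass = sum(tt[i:j]))
        i <- j + 1L
      } else i <- i + 1L
    }
    res
  }
  t_obs <- tser(diffs)
  obs <- cluster_masses(t_obs)
  null_max <- with_seed(seed, vapply(seq_len(n_perm), function(p) {
    flips <- sample(c(-1, 1), n_sub, replace = TRUE)
    cm <- cluster_masses(tser(diffs * flips))
    if (length(cm) == 0) 0 else max(abs(vapply(cm, `[[`, 0, "mass")))
  }, numeric(1)))
  clusters <- if (length(obs) == 0) {
    data.frame(start = numeric(0), end = numeric(0), mass = numeric(0),
               p = numeric(0), significant = logical(0))
  } else {
    do.call(rbind, lapply(obs, function(cl) {
      p <- (1 + sum(null_max >= abs(cl[["mass"]]))) / (n_perm + 1)
      data.frame(start = time[cl[["start"]]], end = time[cl[["end"]]],
                 mass = cl[["mass"]], p = p, significant = p < alpha)
    }))
  }
  structure(list(clusters = clusters, threshold = thr, n_perm = n_perm,
                 t = t_obs, time = time, alpha = alpha,
                 threshold_default = is.null(cluster_threshold)),
            class = "cluster_test")
}

#' @export
print.cluster_test <- function(x, ...) {
  cat(sprintf("<cluster_test> |t| threshold %.3f, %d permutations\n",
              x$threshold, x$n_perm))
  if (nrow(x$clusters) == 0) cat("  no supra-threshold clusters\n")
  else print(x$clusters, row.names = FALSE)
  invisible(x)
}
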