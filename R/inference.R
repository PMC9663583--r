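#' Run the full state-discovery pipeline on a trialset
#'
#' Convenience wrapper: time-delay embedding, PCA compression, HMM fit and
#' decoding, with all dimensions taken from a [pipeline_config()].
#'
#' @param t A [trialset()].
#' @param config A [pipeline_config()].
#' @param n_restarts,max_iter Overrides for [fit_hmm()] (defaults 5, 500).
#' @param seed Seed for the HMM restarts (default derives from the config's
#'   `rng_seed`).
#' @return List: `embedding`, `pca`, `scores`, `model`, `posterior`,
#'   `metrics`, `config`.
#' @export
fit_state_pipeline <- function(t, config = pipeline_config(fs = t$fs),
                               n_restarts = 5, max_iter = 500, seed = NULL) {
  e <- embed_delays(t, config$window_ms)
  pca <- fit_pca(e, config$n_pcs)
  scores <- project_pca(pca, e)
  m <- fit_hmm(scores, e$lengths, config$n_states,
               n_restarts = n_restarts, max_iter = max_iter,
               seed = seed %||% derive_seed(config$rng_seed, "fit_hmm"))
  post <- decode_states(m, scores, e$lengths, index = e$index)
  metrics <- state_metrics(post, t$fs)
  list(embedding = e, pca = pca, scores = scores, model = m,
       posterior = post, metrics = metrics, config = config)
}

#' Pairwise occupancy comparisons within conditions
#'
#' Within each condition, tests every state pair for a difference in
#' fractional occupancy. The unit of analysis is the subject (per-subject
#' mean FO within the condition); the statistic is the difference of
#' medians, and the null exchanges the two compared states' FO values
#' independently per unit (under the null the two states' occupancies are
#' exchangeable). Two-tailed p-values are Benjamini-Hochberg adjusted
#' across all condition x pair comparisons.
#'
#' @param metrics A `state_metrics`, or a trials x K FO matrix.
#' @param condition Per-trial condition labels.
#' @param subject Per-trial subject ids (aggregated to subject means); pass
#'   `NULL` to use trials as units.
#' @param n_perm Number of permutations (default 2000).
#' @param seed Integer seed.
#' @return Data frame: condition, state_a, state_b, median_diff, p, p_adj.
#' @export
fo_condition_tests <- function(metrics, condition, subject = NULL,
                               n_perm = 2000, seed = 1L) {
  fo <- if (inherits(metrics, "state_metrics")) metrics$fo else as.matrix(metrics)
  condition <- factor(condition)
  stopifnot(nrow(fo) == length(condition))
  K <- ncol(fo)
  out <- list()
  with_seed(seed, {
    for (cond in levels(condition)) {
      sel <- which(condition == cond)
      if (length(sel) < 2) {
        warning(sprintf("condition %s has fewer than 2 trials; skipped", cond))
        next
      }
      m <- fo[sel, , drop = FALSE]
      if (!is.null(subject)) {
        sub <- subject[sel]
        m <- apply(m, 2, function(col) tapply(col, sub, mean))
        if (is.null(dim(m))) m <- matrix(m, nrow = 1)
      }
      n <- nrow(m)
      for (a in seq_len(K - 1)) for (b in (a + 1):K) {
        obs <- stats::median(m[, a]) - stats::median(m[, b])
        null <- vapply(seq_len(n_perm), function(r) {
          swap <- stats::runif(n) < 0.5
          xa <- ifelse(swap, m[, b], m[, a])
          xb <- ifelse(swap, m[, a], m[, b])
          stats::median(xa) - stats::median(xb)
        }, numeric(1))
        p <- (1 + sum(abs(null) >= abs(obs))) / (n_perm + 1)
        out[[length(out) + 1L]] <- data.frame(
          condition = cond, state_a = a, state_b = b,
          median_diff = obs, p = p)
      }
    }
  })
  res <- do.call(rbind, out)
  res$p_adj <- stats::p.adjust(res$p, method = "BH")
  res
}

#' Cross-validated decoding of percept type from state occupancies
#'
#' Linear support-vector classification of a binary target (dominant vs
#' mixed upcoming percept) from trial-wise fractional occupancies, with
#' stratified k-fold cross-validation repeated over a log-spaced
#' regularisation grid (default 10^-5 to 10^0 in steps of 0.2 on the log10
#' scale: 26 values). Reports the mean and SD of fold accuracies per grid
#' value, the best grid accuracy, and a "converged" accuracy — the mean
#' over the contiguous upper tail of the grid whose accuracies stay within
#' one fold-SE of the maximum (the plateau where the score has improved
#' and stabilised).
#'
#' @param features Trials x K numeric matrix (FO values).
#' @param target Binary labels (factor or coercible), length = trials.
#' @param folds Number of stratified CV folds (default 5).
#' @param grid Regularisation values (SVM cost); default
#'   `10^seq(-5, 0, by = 0.2)`.
#' @param seed Integer seed for fold assignment.
#' @return A `decode_result` list: `grid`, `accuracy` (mean per value),
#'   `sd` (across folds), `best` (list value/accuracy/sd),
#'   `converged_accuracy`, `folds`, `n`.
#' @export
crossval_decode <- function(features, target, folds = 5,
                            grid = 10^seq(-5, 0, by = 0.2), seed = 1L) {
  features <- as.matrix(features)
  target <- factor(target)
  if (nlevels(target) != 2) stop("target must have exactly 2 classes")
  stopifnot(nrow(features) == length(target), folds >= 2)
  stopifnot(!is.unsorted(grid, strictly = TRUE))
  n <- nrow(features)
  # stratified fold assignment
  fold_id <- integer(n)
  with_seed(seed, {
    for (cl in levels(target)) {
      idx <- sample(which(target == cl))
      fold_id[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  acc <- matrix(NA_real_, folds, length(grid))
  for (f in seq_len(folds)) {
    tr <- fold_id != f; te <- !tr
    for (gi in seq_along(grid)) {
      fit <- e1071::svm(features[tr, , drop = FALSE], target[tr],
                        kernel = "linear", cost = grid[gi], scale = FALSE)
      pred <- stats::predict(fit, features[te, , drop = FALSE])
      acc[f, gi] <- mean(pred == target[te])
    }
  }
  mean_acc <- colMeans(acc)
  sd_acc <- apply(acc, 2, stats::sd)
  bi <- which.max(mean_acc)
  se <- sd_acc[bi] / sqrt(folds)
  # contiguous upper tail of the grid within one fold-SE of the maximum
  tail_ok <- rev(cumprod(rev(mean_acc >= max(mean_acc) - se))) == 1
  structure(list(grid = grid, accuracy = mean_acc, sd = sd_acc,
                 best = list(value = grid[bi], accuracy = mean_acc[bi],
                             sd = sd_acc[bi]),
                 converged_accuracy = mean(mean_acc[tail_ok]),
                 folds = folds, n = n),
            class = "decode_result")
}

#' @export
print.decode_result <- function(x, ...) {
  cat(sprintf("<decode_result> %d-fold CV over %d grid values, n = %d\n",
              x$folds, length(x$grid), x$n))
  cat(sprintf("  best: %.2f%% (SD %.2f%%) at cost %.3g; converged: %.2f%%\n",
              100 * x$best$accuracy, 100 * x$best$sd, x$best$value,
              100 * x$converged_accuracy))
  invisible(x)
}

#' Match states across two fitted models
#'
#' Computes the Pearson correlation between the vectorised state
#' covariances of two models and finds the state pairing that maximises
#' total similarity by exact optimal assignment (all permutations are
#' scored; K is small). Reports the matched per-pair correlations and the
#' matched-minus-unmatched mean-similarity contrast.
#'
#' @param a,b `state_model` objects with equal K and dimension.
#' @return A `match_result` list: `permutation` (state k of `a` matches
#'   state `permutation[k]` of `b`), `similarity` (K x K Pearson matrix),
#'   `matched_r`, `mean_matched`, `mean_unmatched`, `contrast`.
#' @export
match_states <- function(a, b) {
  if (a$K != b$K) stop("models have different numbers of states")
  if (a$d != b$d) stop("models have different dimensions")
  K <- a$K
  va <- vapply(a$covariances, as.vector, numeric(a$d^2))
  vb <- vapply(b$covariances, as.vector, numeric(b$d^2))
  sim <- stats::cor(va, vb)
  perms <- all_permutations(K)
  scores <- vapply(seq_len(nrow(perms)), function(i)
    sum(sim[cbind(seq_len(K), perms[i, ])]), numeric(1))
  best <- perms[which.max(scores), ]
  matched <- sim[cbind(seq_len(K), best)]
  mask <- matrix(TRUE, K, K)
  mask[cbind(seq_len(K), best)] <- FALSE
  structure(list(permutation = best, similarity = sim, matched_r = matched,
                 mean_matched = mean(matched),
                 mean_unmatched = mean(sim[mask]),
                 contrast = mean(matched) - mean(sim[mask])),
            class = "match_result")
}

#' Half-split reliability of the discovered states
#'
#' Randomly splits subjects into two halves, fits the state model
#' independently on each half, matches the states across the two fits, and
#' repeats. Reliable state discovery shows matched similarities well above
#' the unmatched ones; a paired t-test across repeats of matched-vs-
#' unmatched mean similarity summarises the contrast.
#'
#' @param t A [trialset()] with at least 4 subjects.
#' @param config A [pipeline_config()].
#' @param n_repeats Number of random half-splits (default 5).
#' @param n_restarts,max_iter Passed to [fit_hmm()] for the half fits.
#' @param seed Integer seed.
#' @return A `halfsplit_result` list: `matches` (list of `match_result`),
#'   `mean_matched`, `mean_unmatched` (per repeat), `t`, `p` (paired
#'   one-sided t-test matched > unmatched), `n_repeats`.
#' @export
halfsplit_reliability <- function(t, config = pipeline_config(fs = t$fs),
                                  n_repeats = 5, n_restarts = 3,
                                  max_iter = 200, seed = 1L) {
  subs <- unique(t$subject)
  if (length(subs) < 4) stop("need at least 4 subjects to split")
  fit_half <- function(sel, sd) {
    keep <- t$subject %in% sel
    th <- trialset(t$data[keep, , , drop = FALSE], t$fs, t$channels,
                   as.character(t$condition[keep]), t$subject[keep],
                   t$event_sample[keep])
    fit_state_pipeline(th, config, n_restarts = n_restarts,
                       max_iter = max_iter, seed = sd)$model
  }
  matches <- vector("list", n_repeats)
  for (r in seq_len(n_repeats)) {
    half <- with_seed(derive_seed(seed, paste0("halfsplit_", r)),
                      sample(subs, floor(length(subs) / 2)))
    m1 <- fit_half(half, derive_seed(seed, paste0("half_a_", r)))
    m2 <- fit_half(setdiff(subs, half), derive_seed(seed, paste0("half_b_", r)))
    matches[[r]] <- match_states(m1, m2)
  }
  mm <- vapply(matches, `[[`, 0, "mean_matched")
  mu <- vapply(matches, `[[`, 0, "mean_unmatched")
  tt <- stats::t.test(mm, mu, paired = TRUE, alternative = "greater")
  structure(list(matches = matches, mean_matched = mm, mean_unmatched = mu,
                 t = unname(tt$statistic), p = tt$p.value,
                 n_repeats = n_repeats),
            class = "halfsplit_result")
}
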