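#' Fit an autoregressive model, optionally augmented with a second series
#'
#' Least-squares fit of `x(t) = sum_{j=1}^{p} b11_j x(t-j) + e(t)` (the
#' null model) or, when `x2` is supplied, of the augmented model that adds
#' cross-lagged regressors `sum_{j=0}^{p} b12_j x2(t-j)` — note the
#' instantaneous j = 0 term is part of the augmented model by default.
#' The fit runs over `t = maxlag+1 .. T` and reports
#' `BIC = n log(RSS/n) + k log(n)` with `n` the effective sample count
#' after lag truncation and `k` the number of free coefficients.
#'
#' @param x Target series.
#' @param p Autoregressive order (>= 1).
#' @param x2 Optional source series of equal length.
#' @param include_instantaneous Include the j = 0 cross term (default TRUE).
#' @param first_t First predicted time index (default `p + 1`). [gc_dbic()]
#'   passes a common `p_max + 1` so that all candidate models share one
#'   effective sample, making their BICs directly comparable and the BIC
#'   differences invariant to rescaling the series.
#' @return An `ar_model` list: `order`, `coef` (named), `residuals`,
#'   `sigma2`, `bic`, `n_eff`, `k`, `augmented`.
#' @export
fit_ar <- function(x, p, x2 = NULL, include_instantaneous = TRUE,
                   first_t = p + 1) {
  stopifnot(p >= 1, first_t >= p + 1)
  stop_if_not_finite(x, "target series")
  T_ <- length(x)
  k <- if (is.null(x2)) p else p + (p + as.integer(include_instantaneous))
  if (T_ <= 3 * k)
    stop(sprintf("series too short (%d) for %d coefficients", T_, k))
  tt <- first_t:T_
  design <- sapply(seq_len(p), function(j) x[tt - j])
  cn <- paste0("b11_", seq_len(p))
  if (!is.null(x2)) {
    stopifnot(length(x2) == T_)
    stop_if_not_finite(x2, "source series")
    js <- if (include_instantaneous) 0:p else seq_len(p)
    design <- cbind(design, sapply(js, function(j) x2[tt - j]))
    cn <- c(cn, paste0("b12_", js))
  }
  colnames(design) <- cn
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    dropped <- cn[-qrd$pivot[seq_len(qrd$rank)]]
    stop(sprintf("singular design matrix; collinear lag terms: %s",
                 paste(dropped, collapse = ", ")))
  }
  coef <- qr.coef(qrd, x[tt])
  res <- x[tt] - design %*% coef
  n_eff <- length(tt)
  rss <- sum(res^2)
  bic <- n_eff * log(rss / n_eff) + ncol(design) * log(n_eff)
  structure(list(order = p, coef = coef, residuals = as.vector(res),
                 sigma2 = rss / n_eff, bic = bic, n_eff = n_eff,
                 k = ncol(design), augmented = !is.null(x2)),
            class = "ar_model")
}

#' Granger-causal effect size by BIC model comparison
#'
#' The null model is the target's own autoregression at the order `p*`
#' minimising its BIC over `1..p_max`; the augmented model adds the source
#' series' lags `j = 0..p` for every `p` in `1..p_max`. The per-lag effect
#' `dBIC_p = BIC_null(p*) - BIC_aug(p)` is averaged over all `p` to give a
#' lag-agnostic effect size: positive means the source's past (and present)
#' improves the model evidence for the target beyond the target's own past,
#' i.e. evidence that the source Granger-causes the target. Both series are
#' demeaned before fitting.
#'
#' @param target,source Equal-length finite series.
#' @param p_max Maximum lag (default 20 samples, i.e. 80 ms at 250 Hz).
#' @param include_instantaneous Include the j = 0 cross term (default TRUE;
#'   set FALSE for the conventional Granger formulation).
#' @return A `gc_result` list: `dbic` (mean over p), `p_star`, `dbic_trace`
#'   (per-p values), `bic_null`.
#' @export
gc_dbic <- function(target, source, p_max = 20, include_instantaneous = TRUE) {
  stopifnot(length(target) == length(source))
  if (length(target) <= 3 * (2 * p_max + 1))
    stop("series too short for the requested maximum lag")
  target <- target - mean(target)
  source <- source - mean(source)
  # all models share the effective sample t = p_max+1..T so their BICs are
  # directly comparable (and the dBIC is invariant to common rescaling)
  bic_null <- vapply(seq_len(p_max), function(p)
    fit_ar(target, p, first_t = p_max + 1)$bic, numeric(1))
  p_star <- which.min(bic_null)
  trace <- vapply(seq_len(p_max), function(p)
    bic_null[p_star] - fit_ar(target, p, source,
                              include_instantaneous = include_instantaneous,
                              first_t = p_max + 1)$bic,
    numeric(1))
  structure(list(dbic = mean(trace), p_star = p_star, dbic_trace = trace,
                 bic_null = bic_null),
            class = "gc_result")
}

#' Per-trial directed Granger effect over a trialset
#'
#' Computes [gc_dbic()] for one directed channel pair on every trial,
#' returning a per-trial effect-size table keyed by trial index.
#'
#' @param t A [trialset()].
#' @param src,dst Source and target channel labels.
#' @param p_max Maximum lag in samples.
#' @param include_instantaneous See [gc_dbic()].
#' @return Data frame: trial, subject, condition, dbic, p_star.
#' @export
gc_trialset <- function(t, src = "PCU", dst = "V1", p_max = 20,
                        include_instantaneous = TRUE) {
  is_ <- match(src, t$channels); id <- match(dst, t$channels)
  if (anyNA(c(is_, id))) stop("unknown channel label")
  n_trials <- dim(t$data)[1]
  res <- lapply(seq_len(n_trials), function(i) {
    g <- gc_dbic(t$data[i, , id], t$data[i, , is_], p_max = p_max,
                 include_instantaneous = include_instantaneous)
    data.frame(trial = i, subject = t$subject[i],
               condition = as.character(t$condition[i]),
               dbic = g$dbic, p_star = g$p_star)
  })
  do.call(rbind, res)
}
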