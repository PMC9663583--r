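#' Summary statistics of a heavy-tailed duration distribution
#'
#' Sample median, adjusted Fisher-Pearson skewness and excess kurtosis
#' (normal distribution = 0), the summaries conventionally reported for
#' percept-duration distributions.
#'
#' @param durations Numeric vector (>= 3 values, non-constant).
#' @return Named list: `median`, `skewness`, `kurtosis` (excess), `n`.
#' @export
duration_summary <- function(durations) {
  durations <- durations[is.finite(durations)]
  if (length(durations) < 3) stop("need at least 3 values")
  if (stats::sd(durations) == 0) stop("zero variance: skewness undefined")
  list(median = stats::median(durations),
       skewness = e1071::skewness(durations, type = 2),
       kurtosis = e1071::kurtosis(durations, type = 2),
       n = length(durations))
}

# deviance-based R^2 of a fitted glm
glm_r2 <- function(fit) 1 - fit$deviance / fit$null.deviance

#' Gamma GLM of percept duration on state lifetime, directed coupling and
#' their interaction
#'
#' Fits `duration ~ lifetime * gc` with a gamma error distribution and log
#' link (durations are positive and right-skewed), either per trial or on
#' subject means (the unit used for population-level inference). Cohen's
#' f-squared for the interaction is computed against the no-interaction
#' model on deviance-based R-squared:
#' `f2 = (R2_full - R2_reduced) / (1 - R2_full)`.
#'
#' @param b Data frame with columns `duration`, `lifetime`, `gc` and, for
#'   `level = "subject"`, a `subject` column.
#' @param level `"trial"` (default) or `"subject"` (aggregate means first).
#' @return A `glm_fit` list: `coef` (coefficient table with estimate, se,
#'   t, p), `aic`, `f2`, `df_residual`, `fit` (full glm), `reduced`
#'   (no-interaction glm), `level`, `n`.
#' @export
fit_interaction_glm <- function(b, level = c("trial", "subject")) {
  level <- match.arg(level)
  stopifnot(all(c("duration", "lifetime", "gc") %in% names(b)))
  if (level == "subject") {
    agg <- stats::aggregate(b[c("duration", "lifetime", "gc")],
                            by = list(subject = b$subject), FUN = mean)
    b <- agg
  }
  if (nrow(b) < 10) stop("need at least 10 rows")
  if (any(b$duration <= 0)) stop("durations must be positive for a gamma GLM")
  stop_if_not_finite(as.matrix(b[c("duration", "lifetime", "gc")]), "predictors")
  full <- stats::glm(duration ~ lifetime * gc, data = b,
                     family = stats::Gamma(link = "log"))
  reduced <- stats::glm(duration ~ lifetime + gc, data = b,
                        family = stats::Gamma(link = "log"))
  sm <- summary(full)
  coef <- as.data.frame(sm$coefficients)
  names(coef) <- c("estimate", "se", "t", "p")
  r2f <- glm_r2(full); r2r <- glm_r2(reduced)
  structure(list(coef = coef, aic = stats::AIC(full),
                 f2 = max(0, (r2f - r2r) / (1 - r2f)),
                 df_residual = full$df.residual,
                 fit = full, reduced = reduced, level = level, n = nrow(b)),
            class = "glm_fit")
}

#' @export
print.glm_fit <- function(x, ...) {
  cat(sprintf("<glm_fit> gamma/log %s-level, n = %d, AIC = %.2f, f2 = %.3f\n",
              x$level, x$n, x$aic, x$f2))
  print(round(x$coef, 4))
  invisible(x)
}

#' AIC difference between nested models
#'
#' `dAIC = AIC(reduced) - AIC(full)`: positive values favour the full
#' (interaction) model.
#'
#' @param full,reduced Fitted models (`glm_fit` or `glm` objects) on the
#'   same response vector.
#' @return Numeric dAIC.
#' @export
compare_aic <- function(full, reduced) {
  gf <- if (inherits(full, "glm_fit")) full$fit else full
  gr <- if (inherits(reduced, "glm_fit")) reduced$fit else reduced
  if (length(gf$y) != length(gr$y))
    stop("models were fitted to different numbers of observations")
  stats::AIC(gr) - stats::AIC(gf)
}

#' Individual-difference comparison: subject intercepts vs pooled intercept
#'
#' Compares a fixed subject-intercept gamma GLM against the pooled model by
#' AIC and a chi-squared deviance test, quantifying whether durations
#' differ systematically across subjects.
#'
#' @param b Data frame with `duration` and `subject` columns.
#' @return List: `daic` (positive favours subject intercepts), `chisq`,
#'   `df`, `p`.
#' @export
subject_effect_test <- function(b) {
  stopifnot(all(c("duration", "subject") %in% names(b)))
  if (length(unique(b$subject)) < 2) stop("need at least 2 subjects")
  pooled <- stats::glm(duration ~ 1, data = b, family = stats::Gamma(link = "log"))
  bysub <- stats::glm(duration ~ factor(subject), data = b,
                      family = stats::Gamma(link = "log"))
  an <- stats::anova(pooled, bysub, test = "Chisq")
  list(daic = stats::AIC(pooled) - stats::AIC(bysub),
       chisq = an$Deviance[2], df = an$Df[2],
       p = an$`Pr(>Chi)`[2])
}
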