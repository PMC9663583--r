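#' Derive a child seed for a named pipeline stage
#'
#' All stochastic stages draw their RNG seed deterministically from one
#' global seed and the stage name, so a whole pipeline run is reproducible
#' from a single integer while stages stay statistically decoupled.
#'
#' @param seed Integer global seed.
#' @param stage Character scalar naming the stage (e.g. `"fit_hmm"`).
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  codes <- utf8ToInt(stage)
  h <- 0
  for (v in codes) h <- (h * 131 + v) %% 2147483647
  s <- ((abs(seed) %% 2147483647) * 48271) %% 2147483647
  as.integer((s + h) %% 2147483647)
}

# evaluate expr with a local RNG state seeded at `seed`
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# population standard deviation (divides by n, not n-1)
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

stop_if_not_finite <- function(x, what) {
  if (!all(is.finite(x)))
    stop(sprintf("non-finite values in %s", what), call. = FALSE)
  invisible(x)
}
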