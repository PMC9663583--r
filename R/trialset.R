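#' Trial-wise multichannel time-series container
#'
#' A `trialset` holds trial-segmented source signals as a numeric array of
#' dimension trials x samples x channels, together with the sampling rate,
#' ordered channel labels, a per-trial condition label, a per-trial subject
#' identifier, and the within-trial sample index of the behavioural response
#' event. Times are reported in seconds relative to that event (negative =
#' pre-response).
#'
#' @param data Numeric array, trials x samples x channels; all values finite.
#' @param fs Sampling rate in Hz (> 0).
#' @param channels Character vector of unique channel (ROI) labels, length
#'   equal to `dim(data)[3]`.
#' @param condition Per-trial condition label; coerced to factor. The study
#'   design uses the four levels `r paste(condition_levels(), collapse=", ")`,
#'   but any label set is accepted.
#' @param subject Per-trial subject identifier.
#' @param event_sample Integer sample index (1-based) of the response event
#'   within each trial; scalar or per-trial vector.
#' @param meta Optional named list of extra metadata, preserved on disk.
#' @return An object of class `trialset`.
#' @export
trialset <- function(data, fs, channels, condition, subject,
                     event_sample = dim(data)[2], meta = list()) {
  if (length(dim(data)) != 3L) stop("data must be a trials x samples x channels array")
  n_trials <- dim(data)[1]
  if (n_trials == 0L) stop("no trials")
  stop_if_not_finite(data, "trial data")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) stop("fs must be a positive scalar")
  if (length(channels) != dim(data)[3]) stop("channel labels do not match data")
  if (anyDuplicated(channels)) stop("channel labels must be unique")
  if (length(condition) != n_trials) stop("condition labels do not match trial count")
  if (length(subject) != n_trials) stop("subject ids do not match trial count")
  if (length(event_sample) == 1L) event_sample <- rep(event_sample, n_trials)
  if (length(event_sample) != n_trials) stop("event_sample does not match trial count")
  if (any(event_sample < 1L | event_sample > dim(data)[2]))
    stop("event_sample outside trial")
  structure(list(
    data = data, fs = fs, channels = as.character(channels),
    condition = factor(condition), subject = as.character(subject),
    event_sample = as.integer(event_sample), meta = meta
  ), class = "trialset")
}

#' The four condition labels of the bistable-perception design
#'
#' Dominant and mixed percepts, each generated either endogenously
#' (binocular rivalry, BR) or exogenously (replay, RPL).
#' @return Character vector of length 4.
#' @export
condition_levels <- function() c("BR_dom", "BR_mix", "RPL_dom", "RPL_mix")

#' Per-condition epoch counts of the source study
#'
#' The number of 1.1-s pre-response epochs available per condition in the
#' deposited EEG dataset; used by [simulate_study()] to apportion synthetic
#' trials across conditions with the study's proportions.
#' @return Named integer vector over [condition_levels()].
#' @export
study_epoch_counts <- function() {
  c(BR_dom = 7795L, RPL_dom = 7148L, BR_mix = 5786L, RPL_mix = 5038L)[condition_levels()]
}

#' @export
print.trialset <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<trialset> %d trials x %d samples x %d channels @ %g Hz\n",
              d[1], d[2], d[3], x$fs))
  cat("  channels:", paste(x$channels, collapse = ", "), "\n")
  cat("  conditions:", paste(sprintf("%s(%d)", levels(x$condition),
                                     tabulate(x$condition)), collapse = " "), "\n")
  cat(sprintf("  subjects: %d\n", length(unique(x$subject))))
  invisible(x)
}

#' @export
dim.trialset <- function(x) dim(x$data)

#' Trial time axis in seconds relative to the response event
#' @param t A `trialset`.
#' @param trial Trial index whose event anchors the axis (default 1).
#' @return Numeric vector of length `dim(t)[2]`; negative = pre-response.
#' @export
trial_times <- function(t, trial = 1L) {
  (seq_len(dim(t$data)[2]) - t$event_sample[trial]) / t$fs
}

TRIALSET_FORMAT_VERSION <- "1.0"

#' Write a trialset to a directory
#'
#' The signal array is stored as little-endian float64 (`data.bin`,
#' trial-major order) and all metadata in a JSON sidecar (`meta.json`)
#' recording the array dimensions, sampling rate, channel labels, per-trial
#' labels and a format version, so the directory is self-describing. Unknown
#' extra metadata in `t$meta` is preserved verbatim.
#'
#' @param t A `trialset`.
#' @param path Directory to create/write into.
#' @return `path`, invisibly.
#' @export
write_trialset <- function(t, path) {
  stopifnot(inherits(t, "trialset"))
  stop_if_not_finite(t$data, "trial data")
  if (dim(t$data)[1] == 0L) stop("no trials")
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(path)) stop(sprintf("cannot create directory '%s'", path))
  con <- file(file.path(path, "data.bin"), "wb")
  on.exit(close(con), add = TRUE)
  writeBin(as.vector(t$data), con, size = 8L, endian = "little")
  meta <- list(
    format = "statedyn.trialset", version = TRIALSET_FORMAT_VERSION,
    dim = dim(t$data), fs = t$fs, channels = t$channels,
    condition = as.character(t$condition), subject = t$subject,
    event_sample = t$event_sample, extra = t$meta
  )
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a trialset from a directory written by [write_trialset()]
#'
#' @param path Directory containing `data.bin` and `meta.json`.
#' @return A `trialset`; all container invariants are re-validated, and a
#'   corrupted array is refused naming the first offending trial.
#' @export
read_trialset <- function(path) {
  mpath <- file.path(path, "meta.json")
  bpath <- file.path(path, "data.bin")
  if (!file.exists(mpath)) stop("missing meta.json")
  if (!file.exists(bpath)) stop("missing array file data.bin")
  meta <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  if (!identical(meta$format, "statedyn.trialset"))
    stop("not a statedyn trialset directory")
  if (!identical(as.character(meta$version), TRIALSET_FORMAT_VERSION))
    warning(sprintf("trialset format version mismatch: file %s, reader %s",
                    meta$version, TRIALSET_FORMAT_VERSION))
  dims <- as.integer(meta$dim)
  if (length(dims) != 3L) stop("invalid dimensions in sidecar")
  n <- prod(dims)
  con <- file(bpath, "rb")
  on.exit(close(con), add = TRUE)
  vals <- readBin(con, "double", n = n + 1L, size = 8L, endian = "little")
  if (length(vals) != n)
    stop(sprintf("array size mismatch: sidecar declares %d values, file has %d",
                 n, length(vals)))
  if (length(meta$channels) != dims[3])
    stop(sprintf("shape mismatch: sidecar declares %d channels, array has %d",
                 length(meta$channels), dims[3]))
  arr <- array(vals, dim = dims)
  if (!all(is.finite(arr))) {
    bad <- which(apply(!is.finite(arr), 1, any))[1]
    stop(sprintf("non-finite values in stored array (first at trial %d)", bad))
  }
  trialset(arr, fs = as.numeric(meta$fs), channels = meta$channels,
           condition = meta$condition, subject = meta$subject,
           event_sample = meta$event_sample,
           meta = as.list(meta$extra %||% list()))
}

#' Pipeline configuration
#'
#' Bundles the tunable parameters of the full analysis with the defaults
#' used throughout: a 60-ms embedding window (15 samples at 250 Hz), 16
#' principal components (twice the 8 analysis channels), K = 4 states,
#' 2000/5000 permutations for occupancy and spectral tests, autoregressive
#' lags up to 20 samples for Granger causality, and 5-fold cross-validation
#' over a 26-point log-spaced regularisation grid.
#'
#' @param fs Sampling rate, Hz.
#' @param window_ms Embedding window length, ms; must map to an odd sample
#'   count of at least 3.
#' @param n_pcs Number of principal components retained.
#' @param n_states Number of hidden states K (>= 2).
#' @param n_perm_fo Permutations for occupancy tests.
#' @param n_perm_spectra Permutations for spectral feature tests.
#' @param gc_max_lag Maximum autoregressive lag (samples).
#' @param cv_folds Cross-validation folds.
#' @param cv_grid_log10 Lower bound, upper bound and step of the decoder's
#'   regularisation grid on the log10 scale.
#' @param rng_seed Global seed; stage seeds derive from it via [derive_seed()].
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(fs = 250, window_ms = 60, n_pcs = 16, n_states = 4,
                            n_perm_fo = 2000, n_perm_spectra = 5000,
                            gc_max_lag = 20, cv_folds = 5,
                            cv_grid_log10 = c(-5, 0, 0.2), rng_seed = 1L) {
  w <- round(window_ms * fs / 1000)
  if (w < 3 || w %% 2 == 0)
    stop("window_ms x fs must give an odd sample count >= 3 (centred window)")
  if (n_states < 2) stop("n_states must be >= 2")
  counts <- c(n_pcs, n_perm_fo, n_perm_spectra, gc_max_lag, cv_folds)
  if (any(counts <= 0)) stop("all counts must be positive")
  structure(list(fs = fs, window_ms = window_ms, n_pcs = n_pcs,
                 n_states = n_states, n_perm_fo = n_perm_fo,
                 n_perm_spectra = n_perm_spectra, gc_max_lag = gc_max_lag,
                 cv_folds = cv_folds, cv_grid_log10 = cv_grid_log10,
                 rng_seed = rng_seed),
            class = "pipeline_config")
}
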