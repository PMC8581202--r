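#' Construct a set of EEG trials
#'
#' A `trial_set` bundles a three-dimensional array of per-trial EEG
#' (trials x channels x samples, in microvolts) with its sampling rate,
#' per-trial class labels and channel names. It is the common currency of
#' the I/O, preprocessing and simulation functions.
#'
#' Labels follow the package convention for two-class motor imagery:
#' left-hand imagery is `+1`, right-hand imagery is `-1`.
#'
#' @param data numeric array, trials x channels x samples (microvolts).
#' @param fs sampling rate in Hz, positive scalar.
#' @param labels integer-like vector of per-trial labels in `{-1, +1}`,
#'   length equal to the number of trials.
#' @param channel_names character vector naming the channel dimension.
#' @param t0 time of sample 1 relative to the trial start, in seconds.
#'
#' @return An object of class `trial_set` with elements `data`, `fs`,
#'   `labels`, `channel_names` and `t0`.
#' @export
#' @examples
#' ts <- trial_set(array(0, c(2, 3, 8)), fs = 128, labels = c(1, -1),
#'                 channel_names = c("C3", "Cz", "C4"))
#' ts
trial_set <- function(data, fs, labels, channel_names = NULL, t0 = 0) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("'data' must be a 3-d array (trials x channels x samples)")
  storage.mode(data) <- "double"
  dm <- dim(data)
  if (is.null(channel_names))
    channel_names <- paste0("ch", seq_len(dm[2L]))
  ts <- structure(
    list(data = data, fs = as.numeric(fs), labels = as.numeric(labels),
         channel_names = as.character(channel_names), t0 = as.numeric(t0)),
    class = "trial_set")
  validate_trial_set(ts)
  ts
}

#' Validate a trial_set's invariants
#'
#' Checks dimensional consistency, the positivity of the sampling rate and
#' the two-class label coding; stops with a message naming the offending
#' field on the first violation.
#'
#' @param ts a `trial_set`.
#' @return `ts`, invisibly, if valid.
#' @export
validate_trial_set <- function(ts) {
  dm <- dim(ts$data)
  if (length(dm) != 3L)
    stop("data: must be trials x channels x samples")
  if (length(ts$labels) != dm[1L])
    stop(sprintf("labels: %d labels for %d trials", length(ts$labels), dm[1L]))
  if (!all(ts$labels %in% c(-1, 1)))
    stop("labels: every label must be -1 or +1")
  if (!is.numeric(ts$fs) || length(ts$fs) != 1L || !is.finite(ts$fs) || ts$fs <= 0)
    stop("fs: sampling rate must be a positive finite scalar")
  if (length(ts$channel_names) != dm[2L])
    stop(sprintf("channel_names: %d names for %d channels",
                 length(ts$channel_names), dm[2L]))
  if (length(ts$t0) != 1L || !is.finite(ts$t0))
    stop("t0: must be a finite scalar")
  invisible(ts)
}

#' @export
print.trial_set <- function(x, ...) {
  dm <- dim(x$data)
  cat(sprintf("EEG trial set: %d trials x %d channels x %d samples @ %g Hz\n",
              dm[1L], dm[2L], dm[3L], x$fs))
  cat(sprintf("  channels: %s\n", paste(x$channel_names, collapse = ", ")))
  cat(sprintf("  time span: %.3f to %.3f s (t0 = %g)\n",
              x$t0, x$t0 + if (dm[3L] > 0) (dm[3L] - 1) / x$fs else 0, x$t0))
  tab <- table(factor(x$labels, levels = c(1, -1),
                      labels = c("left (+1)", "right (-1)")))
  cat(sprintf("  labels: %s\n",
              paste(sprintf("%s n=%d", names(tab), as.integer(tab)),
                    collapse = ", ")))
  invisible(x)
}

#' Number of trials in a trial_set
#' @param ts a `trial_set`.
#' @return integer trial count.
#' @export
n_trials <- function(ts) dim(ts$data)[1L]

#' Construct a labelled feature matrix
#'
#' Pairs an N x d numeric feature matrix with N labels in `{-1, +1}`; the
#' input contract of the classifiers ([lmsvm()], [idnn()]).
#'
#' @param X numeric matrix, one row per sample.
#' @param y labels in `{-1, +1}`, one per row of `X`.
#' @return An object of class `feature_matrix` with elements `X` and `y`.
#' @export
feature_matrix <- function(X, y) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.numeric(y)
  if (nrow(X) != length(y))
    stop(sprintf("X: %d rows but %d labels", nrow(X), length(y)))
  if (!all(y %in% c(-1, 1)))
    stop("y: every label must be -1 or +1")
  if (anyNA(X) || any(!is.finite(X)))
    stop("X: non-finite entries")
  structure(list(X = X, y = y), class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("feature matrix: %d samples x %d features (%d positive, %d negative)\n",
              nrow(x$X), ncol(x$X), sum(x$y > 0), sum(x$y < 0)))
  invisible(x)
}

# Coerce classifier input: accepts a feature_matrix or a plain matrix + y.
as_xy <- function(x, y = NULL) {
  if (inherits(x, "feature_matrix")) return(list(X = x$X, y = x$y))
  if (is.null(y)) stop("labels 'y' required when 'x' is a plain matrix")
  fm <- feature_matrix(x, y)
  list(X = fm$X, y = fm$y)
}
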