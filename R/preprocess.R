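#' Zero-phase Butterworth band-pass filter
#'
#' Filters every trial and channel with a Butterworth band-pass applied
#' forward and backward (`signal::filtfilt`), so the output has no group
#' delay. The standard wide band for sensorimotor-rhythm work is
#' 0.5--30 Hz; narrow bands (mu 8--12 Hz, beta 18--26 Hz) isolate the
#' rhythms whose event-related desynchronization carries the class signal.
#'
#' @param ts a [trial_set()].
#' @param lo,hi band edges in Hz, `0 <= lo < hi < fs/2`.
#' @param order Butterworth order (default 5).
#' @return A new `trial_set`, same shape, filtered in place.
#' @export
#' @examples
#' ts <- generate_mi_trials(synth_config(n_per_class = 2, seed = 1))
#' filtered <- bandpass(ts, 0.5, 30)
bandpass <- function(ts, lo, hi, order = 5L) {
  validate_trial_set(ts)
  nyq <- ts$fs / 2
  if (!(lo >= 0 && lo < hi)) stop("band edges: need 0 <= lo < hi")
  if (hi >= nyq) stop(sprintf("hi = %g Hz is at or above Nyquist (%g Hz)", hi, nyq))
  dm <- dim(ts$data)
  # filtfilt needs the signal to outlast the filter's edge transient
  if (dm[3L] <= 6L * (2L * order + 1L))
    stop(sprintf("trials of %d samples are too short for an order-%d band-pass",
                 dm[3L], order))
  flt <- signal::butter(order, c(lo, hi) / nyq, type = "pass")
  out <- ts$data
  for (i in seq_len(dm[1L]))
    for (j in seq_len(dm[2L]))
      out[i, j, ] <- signal::filtfilt(flt, ts$data[i, j, ])
  ts$data <- out
  ts
}

#' Extract a fixed time window from every trial
#'
#' Cuts each trial to the `[t_start, t_end)` analysis window (seconds,
#' relative to trial start). The canonical window for the 9-s cue-paced
#' paradigm is 4--9 s, the imagery period after the directional cue.
#'
#' @param ts a [trial_set()].
#' @param t_start,t_end window edges in seconds; must lie inside the
#'   recorded span.
#' @return A `trial_set` with `round((t_end - t_start) * fs)` samples per
#'   trial and `t0` updated to `t_start`.
#' @export
epoch <- function(ts, t_start, t_end) {
  validate_trial_set(ts)
  dm <- dim(ts$data)
  span_end <- ts$t0 + dm[3L] / ts$fs
  if (t_start < ts$t0 || t_end > span_end + 1e-9 || t_start >= t_end)
    stop(sprintf("window [%g, %g] s outside recorded span [%g, %g] s",
                 t_start, t_end, ts$t0, span_end))
  i0 <- round((t_start - ts$t0) * ts$fs) + 1L
  n <- round((t_end - t_start) * ts$fs)
  if (i0 + n - 1L > dm[3L])
    stop("window exceeds the recorded samples")
  ts$data <- ts$data[, , i0:(i0 + n - 1L), drop = FALSE]
  ts$t0 <- t_start
  ts
}

#' Describe a feature extraction scheme
#'
#' Two modes are supported. `"bandpower"` (the default scheme for
#' motor-imagery work) band-passes each trial to each requested band and
#' takes the natural log of the within-window signal variance per channel,
#' giving `channels * bands` features; log band-power is the standard
#' discriminative statistic for event-related desynchronization.
#' `"flatten"` concatenates the (optionally decimated) raw samples,
#' giving `channels * samples / downsample_factor` features.
#'
#' @param mode `"bandpower"` or `"flatten"`.
#' @param bands list of `c(lo, hi)` band edges in Hz (bandpower mode);
#'   defaults to mu (8--12 Hz) and beta (18--26 Hz).
#' @param window analysis window `c(t_start, t_end)` in seconds; trials
#'   are epoched to it before extraction. Default 4--9 s.
#' @param downsample_factor positive integer decimation (flatten mode).
#' @return A list of class `feature_spec`.
#' @export
feature_spec <- function(mode = c("bandpower", "flatten"),
                         bands = list(c(8, 12), c(18, 26)),
                         window = c(4, 9),
                         downsample_factor = 1L) {
  mode <- match.arg(mode)
  if (mode == "bandpower" && length(bands) == 0L)
    stop("bandpower mode needs at least one band")
  for (b in bands)
    if (length(b) != 2L || b[1L] <= 0 || b[1L] >= b[2L])
      stop("each band must be c(lo, hi) with 0 < lo < hi")
  if (length(window) != 2L || window[1L] < 0 || window[1L] >= window[2L])
    stop("window must be c(t_start, t_end) with 0 <= t_start < t_end")
  if (downsample_factor < 1L)
    stop("downsample_factor must be a positive integer")
  structure(list(mode = mode, bands = bands, window = as.numeric(window),
                 downsample_factor = as.integer(downsample_factor)),
            class = "feature_spec")
}

#' Turn EEG trials into a labelled feature matrix
#'
#' Applies a [feature_spec()] to a trial set: epochs to the spec's window
#' then computes either log band-power features or flattened samples.
#' Labels are copied through unchanged.
#'
#' @param ts a [trial_set()] (band-pass filtered as desired).
#' @param spec a [feature_spec()].
#' @return A [feature_matrix()].
#' @export
extract_features <- function(ts, spec = feature_spec()) {
  validate_trial_set(ts)
  stopifnot(inherits(spec, "feature_spec"))
  ts <- epoch(ts, spec$window[1L], spec$window[2L])
  dm <- dim(ts$data)
  if (spec$mode == "bandpower") {
    for (b in spec$bands)
      if (b[2L] >= ts$fs / 2)
        stop(sprintf("band %g-%g Hz exceeds Nyquist (%g Hz)",
                     b[1L], b[2L], ts$fs / 2))
    cols <- vector("list", length(spec$bands))
    for (k in seq_along(spec$bands)) {
      b <- spec$bands[[k]]
      bts <- bandpass(ts, b[1L], b[2L], order = 4L)
      # log variance over the window, per trial x channel
      cols[[k]] <- log(apply(bts$data, c(1L, 2L), stats::var))
    }
    X <- do.call(cbind, cols)
    nm <- as.vector(outer(ts$channel_names,
                          vapply(spec$bands, function(b)
                            sprintf("%g-%gHz", b[1L], b[2L]), ""),
                          paste, sep = "_"))
    colnames(X) <- nm
  } else {
    keep <- seq(1L, dm[3L], by = spec$downsample_factor)
    X <- matrix(NA_real_, dm[1L], dm[2L] * length(keep))
    for (i in seq_len(dm[1L])) {
      sl <- matrix(ts$data[i, , keep, drop = FALSE], dm[2L], length(keep))
      X[i, ] <- as.vector(t(sl))      # per channel, samples contiguous
    }
  }
  feature_matrix(X, ts$labels)
}

#' Fit a z-score normalizer on training features
#'
#' Records per-feature means and standard deviations of the training set;
#' [zscore_apply()] then centres and scales any feature matrix with those
#' training statistics only, keeping held-out data leakage-free. Features
#' with zero training variance get scale 1 (centred only).
#'
#' @param train a [feature_matrix()] with at least 2 rows.
#' @return An object of class `zscore_normalizer`.
#' @export
zscore_fit <- function(train) {
  stopifnot(inherits(train, "feature_matrix"))
  if (nrow(train$X) < 2L) stop("need at least 2 training samples")
  mu <- colMeans(train$X)
  sd <- apply(train$X, 2L, stats::sd)
  sd[!is.finite(sd) | sd <= 0] <- 1
  structure(list(center = mu, scale = sd), class = "zscore_normalizer")
}

#' Apply a fitted z-score normalizer
#'
#' @param norm a normalizer from [zscore_fit()].
#' @param fm a [feature_matrix()] with the same feature dimension.
#' @return The normalized `feature_matrix`.
#' @export
zscore_apply <- function(norm, fm) {
  stopifnot(inherits(norm, "zscore_normalizer"), inherits(fm, "feature_matrix"))
  if (ncol(fm$X) != length(norm$center))
    stop(sprintf("normalizer has %d features, input has %d",
                 length(norm$center), ncol(fm$X)))
  X <- sweep(sweep(fm$X, 2L, norm$center, "-"), 2L, norm$scale, "/")
  feature_matrix(X, fm$y)
}
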