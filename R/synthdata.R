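#' Configuration for the synthetic motor-imagery EEG generator
#'
#' Describes a two-class cue-paced motor-imagery experiment: each 9-s trial
#' carries broadband Gaussian noise on every channel plus a mu-rhythm
#' oscillation on the lateral sensorimotor channels (C3, C4). During the
#' imagery window the mu amplitude on the hemisphere contralateral to the
#' imagined hand is attenuated by a factor `erd_depth` — the event-related
#' desynchronization (ERD) that band-power classifiers exploit. Left-hand
#' trials (label `+1`) attenuate C4, right-hand trials (label `-1`)
#' attenuate C3.
#'
#' Defaults mirror the standard cue-paced paradigm: 140 trials per class
#' (280 total), three channels sampled at 128 Hz for 9 s, imagery from
#' second 4 to second 9, a 10 Hz mu rhythm of 10 microvolt amplitude.
#'
#' @param n_per_class trials per class.
#' @param channels channel names; "C3" and "C4" (if present) carry the mu
#'   oscillation and the lateralized ERD.
#' @param fs sampling rate (Hz).
#' @param duration trial length (s).
#' @param imagery_window numeric length-2, start and end (s) of the
#'   imagery period within the trial.
#' @param mu_freq mu-rhythm frequency (Hz).
#' @param mu_amp baseline mu amplitude (microvolts).
#' @param erd_depth fractional contralateral mu-amplitude reduction during
#'   imagery, in `[0, 1]`; 0 means the two classes are distributionally
#'   identical, 1 means complete suppression.
#' @param noise_sd broadband white-noise standard deviation (microvolts).
#' @param seed integer seed; the generator is deterministic given the
#'   configuration.
#' @return A list of class `synth_config`.
#' @export
#' @examples
#' cfg <- synth_config(n_per_class = 10, seed = 1)
#' ts <- generate_mi_trials(cfg)
#' ts
synth_config <- function(n_per_class = 140,
                         channels = c("C3", "Cz", "C4"),
                         fs = 128, duration = 9,
                         imagery_window = c(4, 9),
                         mu_freq = 10, mu_amp = 10,
                         erd_depth = 0.5, noise_sd = 4,
                         seed = 1L) {
  cfg <- list(n_per_class = as.integer(n_per_class), channels = channels,
              fs = fs, duration = duration,
              imagery_window = as.numeric(imagery_window),
              mu_freq = mu_freq, mu_amp = mu_amp,
              erd_depth = erd_depth, noise_sd = noise_sd,
              seed = as.integer(seed))
  bad <- character(0)
  if (cfg$n_per_class < 1L) bad <- c(bad, "n_per_class: must be >= 1")
  if (length(cfg$channels) < 1L) bad <- c(bad, "channels: need at least one")
  if (!is.finite(cfg$fs) || cfg$fs <= 0) bad <- c(bad, "fs: must be positive")
  if (!is.finite(cfg$duration) || cfg$duration <= 0)
    bad <- c(bad, "duration: must be positive")
  iw <- cfg$imagery_window
  if (length(iw) != 2L || iw[1L] < 0 || iw[2L] <= iw[1L] || iw[2L] > cfg$duration)
    bad <- c(bad, "imagery_window: need 0 <= start < end <= duration")
  if (cfg$mu_freq <= 0 || cfg$mu_freq >= cfg$fs / 2)
    bad <- c(bad, "mu_freq: must lie in (0, fs/2)")
  if (cfg$mu_amp < 0) bad <- c(bad, "mu_amp: must be >= 0")
  if (!is.finite(cfg$erd_depth) || cfg$erd_depth < 0 || cfg$erd_depth > 1)
    bad <- c(bad, "erd_depth: must lie in [0, 1]")
  if (cfg$noise_sd < 0) bad <- c(bad, "noise_sd: must be >= 0")
  if (length(bad)) stop(paste(bad, collapse = "; "))
  structure(cfg, class = "synth_config")
}

#' Simulate two-class motor-imagery EEG trials
#'
#' Generates a [trial_set()] according to a [synth_config()]: white
#' Gaussian noise on every channel, a constant-amplitude mu oscillation
#' with a random phase per trial and channel on C3 and C4, and a
#' lateralized amplitude drop of `erd_depth` during the imagery window on
#' the channel contralateral to the imagined hand. Trials are interleaved
#' left/right and labelled `+1` (left) / `-1` (right).
#'
#' @param cfg a [synth_config()].
#' @return A `trial_set` with `2 * n_per_class` trials.
#' @export
generate_mi_trials <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "synth_config"))
  n_samp <- round(cfg$duration * cfg$fs)
  n_tot <- 2L * cfg$n_per_class
  chans <- cfg$channels
  n_ch <- length(chans)
  tt <- (seq_len(n_samp) - 1) / cfg$fs
  in_imagery <- tt >= cfg$imagery_window[1L] & tt < cfg$imagery_window[2L]
  labels <- rep(c(1, -1), cfg$n_per_class)        # interleaved left/right

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(cfg$seed)

  data <- array(rnorm(n_tot * n_ch * n_samp, sd = cfg$noise_sd),
                dim = c(n_tot, n_ch, n_samp))
  mu_ch <- which(chans %in% c("C3", "C4"))
  for (i in seq_len(n_tot)) {
    # left hand (+1) -> ERD on contralateral right hemisphere (C4);
    # right hand (-1) -> ERD on C3
    erd_name <- if (labels[i] > 0) "C4" else "C3"
    for (ci in mu_ch) {
      amp <- rep(cfg$mu_amp, n_samp)
      if (chans[ci] == erd_name)
        amp[in_imagery] <- cfg$mu_amp * (1 - cfg$erd_depth)
      phase <- runif(1, 0, 2 * pi)
      data[i, ci, ] <- data[i, ci, ] +
        amp * sin(2 * pi * cfg$mu_freq * tt + phase)
    }
  }
  trial_set(data, fs = cfg$fs, labels = labels, channel_names = chans, t0 = 0)
}

#' Simulate two spherical Gaussian classes of features
#'
#' Unit-test fixture for the classifiers: two spherical unit-variance
#' Gaussian classes in `d` dimensions whose means are `separation` pooled
#' standard deviations apart along the first axis. `separation = 0` gives
#' indistinguishable classes (Bayes accuracy 0.5); `separation = 6` gives
#' near-complete separation (normal-tail overlap about 0.13% per side).
#'
#' @param n_per_class samples per class.
#' @param d feature dimension.
#' @param separation class-mean distance in pooled-SD units, `>= 0`.
#' @param seed integer seed.
#' @return A [feature_matrix()] with `2 * n_per_class` rows; class `+1`
#'   centred at `+separation/2` on axis 1, class `-1` at `-separation/2`.
#' @export
generate_gaussian_features <- function(n_per_class, d, separation, seed = 1L) {
  if (n_per_class < 1L || d < 1L) stop("n_per_class and d must be >= 1")
  if (separation < 0) stop("separation must be >= 0")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  n <- 2L * as.integer(n_per_class)
  y <- rep(c(1, -1), n_per_class)
  X <- matrix(rnorm(n * d), n, d)
  X[, 1L] <- X[, 1L] + y * separation / 2
  feature_matrix(X, y)
}

# Save/restore the global RNG state so generators are pure functions of
# their seed argument without clobbering the caller's stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
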