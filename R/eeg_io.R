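#' Read EEG trials from disk
#'
#' Two dialects are supported. `"portable"` is the package's own flat
#' binary container (see Details) and round-trips [trial_set()] objects
#' losslessly. `"competition_mat"` reads a MATLAB v5 `.mat` file holding
#' cue-paced motor-imagery trials in the layout used by the Graz BCI
#' competition datasets: a 3-d signal array (trials x samples x channels,
#' 128 Hz, 9-s trials over C3/Cz/C4) plus a label vector coded `{1, 2}`
#' for left/right, remapped here to `{+1, -1}`.
#'
#' @details
#' The portable container is little-endian throughout:
#' \preformatted{
#'   bytes 1-8    magic "EEGTRIAL"
#'   int32        format version (1)
#'   int32 x 3    n_trials, n_channels, n_samples
#'   double x 2   fs (Hz), t0 (s)
#'   int32 x T    labels (-1 / +1)
#'   per channel  int32 byte length, then UTF-8 name bytes
#'   double x TCS data, R column-major order, dims (T, C, S)
#' }
#' All reals are IEEE-754 doubles, so write-then-read is bit-exact.
#'
#' For `"competition_mat"`, the variables `x_train`/`y_train` (or `x`/`y`)
#' are used when present; otherwise the unique 3-d numeric array and the
#' unique vector whose length matches its trial count are taken. The
#' sampling rate is fixed at 128 Hz and channels are named C3, Cz, C4 when
#' the file does not say otherwise.
#'
#' @param path file to read.
#' @param dialect `"portable"` or `"competition_mat"`.
#' @return A [trial_set()].
#' @seealso [write_trials()]
#' @export
read_trials <- function(path, dialect = c("portable", "competition_mat")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  switch(dialect,
         portable = read_trials_portable(path),
         competition_mat = read_trials_competition(path))
}

#' Write EEG trials to the portable container
#'
#' Serializes a [trial_set()] to the flat binary layout documented under
#' [read_trials()]. Writing is deterministic: the same trial set always
#' produces byte-identical files.
#'
#' @param ts a valid [trial_set()].
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_trials <- function(ts, path) {
  validate_trial_set(ts)
  dm <- dim(ts$data)
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeBin(charToRaw("EEGTRIAL"), con)
  writeBin(c(1L, dm), con, size = 4L, endian = "little")
  writeBin(c(ts$fs, ts$t0), con, size = 8L, endian = "little")
  writeBin(as.integer(ts$labels), con, size = 4L, endian = "little")
  for (nm in ts$channel_names) {
    raw_nm <- charToRaw(enc2utf8(nm))
    writeBin(length(raw_nm), con, size = 4L, endian = "little")
    writeBin(raw_nm, con)
  }
  writeBin(as.vector(ts$data), con, size = 8L, endian = "little")
  invisible(path)
}

read_trials_portable <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  magic <- readBin(con, "raw", 8L)
  if (!identical(rawToChar(magic), "EEGTRIAL"))
    stop(sprintf("not a portable trial file (bad magic): %s", path))
  hdr <- readBin(con, "integer", 4L, size = 4L, endian = "little")
  if (hdr[1L] != 1L) stop(sprintf("unsupported format version %d", hdr[1L]))
  dm <- hdr[2:4]
  meta <- readBin(con, "double", 2L, size = 8L, endian = "little")
  labels <- readBin(con, "integer", dm[1L], size = 4L, endian = "little")
  ch <- character(dm[2L])
  for (i in seq_len(dm[2L])) {
    nb <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    ch[i] <- rawToChar(readBin(con, "raw", nb))
  }
  n_val <- prod(dm)
  dat <- readBin(con, "double", n_val, size = 8L, endian = "little")
  if (length(dat) != n_val)
    stop(sprintf("data: expected %d values, file holds %d", n_val, length(dat)))
  trial_set(array(dat, dim = dm), fs = meta[1L], labels = labels,
            channel_names = ch, t0 = meta[2L])
}

read_trials_competition <- function(path) {
  vars <- read_mat5(path)
  pick <- function(names) {
    hit <- intersect(names, names(vars))
    if (length(hit)) vars[[hit[1L]]] else NULL
  }
  x <- pick(c("x_train", "x", "X", "data"))
  y <- pick(c("y_train", "y", "Y", "labels"))
  if (is.null(x)) {
    is3d <- vapply(vars, function(v) length(dim(v)) == 3L, logical(1))
    if (sum(is3d) != 1L)
      stop("data: could not identify a unique trials x samples x channels array")
    x <- vars[[which(is3d)]]
  }
  if (length(dim(x)) != 3L)
    stop("data: expected a 3-d array of trials")
  n_tr <- dim(x)[1L]
  if (is.null(y)) {
    lens <- vapply(vars, function(v)
      if (is.null(dim(v)) || min(dim(v)) == 1L) length(v) else -1L, numeric(1))
    cand <- which(lens == n_tr & !vapply(vars, function(v) length(dim(v)) == 3L,
                                         logical(1)))
    if (length(cand) != 1L)
      stop(sprintf("labels: no unique label vector of length %d found", n_tr))
    y <- vars[[cand]]
  }
  y <- as.numeric(y)
  if (length(y) != n_tr)
    stop(sprintf("labels: %d labels for %d trials", length(y), n_tr))
  uy <- sort(unique(y))
  if (identical(uy, c(1, 2))) y <- ifelse(y == 1, 1, -1)   # 1=left, 2=right
  if (!all(y %in% c(-1, 1)))
    stop("labels: values outside two classes {1,2} / {-1,+1}")
  # competition layout is trials x samples x channels -> reorder
  x <- aperm(x, c(1L, 3L, 2L))
  n_ch <- dim(x)[2L]
  ch <- if (n_ch == 3L) c("C3", "Cz", "C4") else paste0("ch", seq_len(n_ch))
  trial_set(x, fs = 128, labels = y, channel_names = ch, t0 = 0)
}

#' Write trials in the competition MATLAB layout
#'
#' Writes a MATLAB v5 `.mat` file with variables `x_train`
#' (trials x samples x channels, double) and `y_train` (labels coded 1 =
#' left, 2 = right), the layout [read_trials()] expects for the
#' `"competition_mat"` dialect. Useful for exchanging simulated data with
#' MATLAB/Python tooling.
#'
#' @param ts a valid [trial_set()].
#' @param path destination `.mat` file.
#' @return `path`, invisibly.
#' @export
write_trials_competition <- function(ts, path) {
  validate_trial_set(ts)
  x <- aperm(ts$data, c(1L, 3L, 2L))
  y <- matrix(ifelse(ts$labels > 0, 1, 2), ncol = 1L)
  write_mat5(path, list(x_train = x, y_train = y))
  invisible(path)
}
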