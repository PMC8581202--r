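# Minimal MATLAB level-5 MAT-file support: numeric arrays only, little
# endian, compressed elements handled via zlib. This covers the layout of
# the public BCI-competition motor-imagery files (double/int16 signal
# arrays plus an integer label vector); cells, structs, sparse and
# character arrays are out of scope and are skipped with a warning.

MI_TYPE_SIZE <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 2L, `5` = 4L,
                  `6` = 4L, `7` = 4L, `9` = 8L, `12` = 8L, `13` = 8L)

read_mi_numeric <- function(buf, type, nbytes) {
  n <- nbytes %/% MI_TYPE_SIZE[[as.character(type)]]
  switch(as.character(type),
    `1` = as.numeric(readBin(buf, "integer", n, size = 1L, signed = TRUE)),
    `2` = as.numeric(readBin(buf, "integer", n, size = 1L, signed = FALSE)),
    `3` = as.numeric(readBin(buf, "integer", n, size = 2L, signed = TRUE,
                             endian = "little")),
    `4` = as.numeric(readBin(buf, "integer", n, size = 2L, signed = FALSE,
                             endian = "little")),
    `5` = as.numeric(readBin(buf, "integer", n, size = 4L, endian = "little")),
    `6` = {v <- readBin(buf, "integer", n, size = 4L, endian = "little")
           ifelse(v < 0, v + 2^32, v)},
    `7` = readBin(buf, "double", n, size = 4L, endian = "little"),
    `9` = readBin(buf, "double", n, size = 8L, endian = "little"),
    `12` = readBin(buf, "double", n, size = 8L, endian = "little"),  # int64 via double
    `13` = readBin(buf, "double", n, size = 8L, endian = "little"),
    stop(sprintf("unsupported MAT data type %d", type)))
}

# Parse one tagged data element starting at byte offset pos (1-based).
# Returns list(type, payload raw, next position). Handles the packed
# "small data element" format (type and length share the first word).
mat5_element <- function(raw, pos) {
  w1 <- readBin(raw[pos:(pos + 3L)], "integer", 1L, size = 4L, endian = "little")
  small_len <- bitwAnd(bitwShiftR(w1, 16L), 0xFFFFL)
  if (small_len != 0L) {
    type <- bitwAnd(w1, 0xFFFFL)
    payload <- if (small_len > 0L) raw[(pos + 4L):(pos + 3L + small_len)] else raw[0L]
    return(list(type = type, payload = payload, next_pos = pos + 8L))
  }
  type <- w1
  nbytes <- readBin(raw[(pos + 4L):(pos + 7L)], "integer", 1L, size = 4L,
                    endian = "little")
  payload <- if (nbytes > 0L) raw[(pos + 8L):(pos + 7L + nbytes)] else raw[0L]
  adv <- 8L + nbytes
  if (type != 15L) adv <- adv + (-nbytes) %% 8L   # pad to 8-byte boundary
  list(type = type, payload = payload, next_pos = pos + adv)
}

mat5_parse_matrix <- function(body) {
  pos <- 1L
  flags <- mat5_element(body, pos); pos <- flags$next_pos
  fw <- readBin(flags$payload[1:4], "integer", 1L, size = 4L, endian = "little")
  klass <- bitwAnd(fw, 0xFFL)
  is_complex <- bitwAnd(bitwShiftR(fw, 8L), 0x08L) != 0L
  dims_el <- mat5_element(body, pos); pos <- dims_el$next_pos
  dims <- readBin(dims_el$payload, "integer",
                  length(dims_el$payload) %/% 4L, size = 4L, endian = "little")
  name_el <- mat5_element(body, pos); pos <- name_el$next_pos
  name <- rawToChar(name_el$payload)
  if (!(klass %in% 6:13)) {
    warning(sprintf("skipping variable '%s': unsupported MATLAB class %d",
                    name, klass))
    return(list(name = name, value = NULL))
  }
  pr <- mat5_element(body, pos)
  vals <- read_mi_numeric(pr$payload, pr$type, length(pr$payload))
  if (length(vals) != prod(dims))
    stop(sprintf("variable '%s': %d values for dims [%s]",
                 name, length(vals), paste(dims, collapse = "x")))
  if (is_complex)
    warning(sprintf("variable '%s': imaginary part ignored", name))
  value <- if (length(dims) > 2L) array(vals, dims)
           else if (length(dims) == 2L && dims[2L] > 1L && dims[1L] > 1L)
             matrix(vals, dims[1L], dims[2L])
           else as.vector(vals)
  list(name = name, value = value)
}

read_mat5 <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 128L) stop(sprintf("not a MAT v5 file (too short): %s", path))
  endian_tag <- rawToChar(raw[127:128])
  if (endian_tag == "MI")
    stop("big-endian MAT files are not supported")
  if (endian_tag != "IM")
    stop(sprintf("not a MAT v5 file (bad endian tag): %s", path))
  out <- list()
  pos <- 129L
  n_total <- length(raw)
  while (pos + 7L <= n_total) {
    el <- mat5_element(raw, pos)
    if (el$type == 15L) {                       # compressed: zlib-wrapped element
      inner <- memDecompress(el$payload, type = "gzip")
      sub <- mat5_element(inner, 1L)
      if (sub$type == 14L) {
        v <- mat5_parse_matrix(sub$payload)
        if (!is.null(v$value)) out[[v$name]] <- v$value
      }
      pos <- el$next_pos                        # compressed elements are unpadded
    } else if (el$type == 14L) {
      v <- mat5_parse_matrix(el$payload)
      if (!is.null(v$value)) out[[v$name]] <- v$value
      pos <- el$next_pos
    } else {
      pos <- el$next_pos                        # skip non-matrix element
    }
  }
  out
}

# --- writer: uncompressed double arrays, enough to exchange simulated
# trials with scipy.io / MATLAB ---

mat5_raw_element <- function(type, payload) {
  pad <- as.integer((-length(payload)) %% 8L)
  c(writeBin(c(as.integer(type), length(payload)), raw(), size = 4L,
             endian = "little"),
    payload, raw(pad))
}

write_mat5 <- function(path, vars) {
  stopifnot(is.list(vars), length(names(vars)) == length(vars))
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  desc <- sprintf("MATLAB 5.0 MAT-file, written by bcidnn")
  hdr <- charToRaw(formatC(desc, width = -124L))[1:124]
  writeBin(hdr, con)
  writeBin(c(0x00L, 0x01L), con, size = 1L)                 # version 0x0100
  writeBin(charToRaw("IM"), con)
  for (nm in names(vars)) {
    v <- vars[[nm]]
    dims <- dim(v)
    if (is.null(dims)) dims <- c(length(v), 1L)
    flags <- writeBin(c(6L, 0L), raw(), size = 4L, endian = "little")
    body <- c(mat5_raw_element(6L, flags),
              mat5_raw_element(5L, writeBin(as.integer(dims), raw(), size = 4L,
                                            endian = "little")),
              mat5_raw_element(1L, charToRaw(nm)),
              mat5_raw_element(9L, writeBin(as.vector(as.numeric(v)), raw(),
                                            size = 8L, endian = "little")))
    writeBin(c(14L, length(body)), con, size = 4L, endian = "little")
    writeBin(body, con)
  }
  invisible(path)
}
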