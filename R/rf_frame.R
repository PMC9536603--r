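# RF frame container and binary on-disk format.

#' Construct an RF frame
#'
#' An RF frame holds one acquisition: `n_lines` scan lines of raw
#' radiofrequency echo, each with `n_samples` signed 16-bit samples, plus
#' acquisition metadata. Samples are stored as an integer matrix with one
#' row per scan line.
#'
#' @param samples integer matrix, `n_lines x n_samples`, values in
#'   `[-32768, 32767]`.
#' @param sample_rate_hz sampling rate in Hz (default 14 MHz).
#' @param center_freq_hz transducer centre frequency in Hz (default 3.5 MHz).
#' @param sample_id character identifier of the tissue sample.
#' @param temperature_c tissue temperature in degrees Celsius, in `[0, 100]`.
#' @return An object of class `rf_frame`.
#' @export
rf_frame <- function(samples, sample_rate_hz = 14e6, center_freq_hz = 3.5e6,
                     sample_id = "s01", temperature_c = 20) {
  if (!is.matrix(samples)) stop("`samples` must be a matrix")
  storage.mode(samples) <- "integer"
  frame <- structure(
    list(samples = samples,
         sample_rate_hz = sample_rate_hz,
         center_freq_hz = center_freq_hz,
         sample_id = as.character(sample_id),
         temperature_c = as.numeric(temperature_c)),
    class = "rf_frame")
  validate_rf_frame(frame)
  frame
}

validate_rf_frame <- function(frame) {
  s <- frame$samples
  if (anyNA(s)) stop("RF samples contain NA")
  rng <- range(s)
  if (rng[1] < -32768L || rng[2] > 32767L)
    stop("RF samples outside the signed 16-bit range")
  if (frame$temperature_c < 0 || frame$temperature_c > 100)
    stop("temperature_c must lie in [0, 100]")
  invisible(frame)
}

#' @export
print.rf_frame <- function(x, ...) {
  cat(sprintf("<rf_frame> sample %s @ %.1f degC: %d lines x %d samples, fs = %.1f MHz\n",
              x$sample_id, x$temperature_c, nrow(x$samples), ncol(x$samples),
              x$sample_rate_hz / 1e6))
  invisible(x)
}

RF_MAGIC <- "USRF"
RF_VERSION <- 1L

#' Write an RF frame to a binary file
#'
#' The format is little-endian throughout: a 4-byte magic string `"USRF"`,
#' `int32` version (1), `int32` `n_lines`, `int32` `n_samples`, `float64`
#' sample rate (Hz), `float64` centre frequency (Hz), `float64` temperature
#' (degC), `int32` sample-id length followed by that many UTF-8 bytes, then
#' the payload: `n_lines * n_samples` `int16` values, line-major (all
#' samples of scan line 0, then line 1, ...). Round-trips through
#' [read_rf_frame()] are bit-exact.
#'
#' @param frame an [rf_frame()].
#' @param path destination file path.
#' @return `path`, invisibly.
#' @export
write_rf_frame <- function(frame, path) {
  validate_rf_frame(frame)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(RF_MAGIC), con)
  writeBin(c(RF_VERSION, nrow(frame$samples), ncol(frame$samples)), con,
           size = 4L, endian = "little")
  writeBin(c(frame$sample_rate_hz, frame$center_freq_hz, frame$temperature_c),
           con, size = 8L, endian = "little")
  id_raw <- charToRaw(frame$sample_id)
  writeBin(length(id_raw), con, size = 4L, endian = "little")
  writeBin(id_raw, con)
  # line-major payload: R matrices are column-major, so write the transpose
  writeBin(as.integer(t(frame$samples)), con, size = 2L, endian = "little")
  invisible(path)
}

#' Read an RF frame written by [write_rf_frame()]
#'
#' @param path file path.
#' @return An [rf_frame()].
#' @export
read_rf_frame <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 4L))
  if (!identical(magic, RF_MAGIC)) stop("not an RF frame file (bad magic)")
  version <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  if (!identical(version, RF_VERSION))
    stop(sprintf("unsupported RF frame version %d", version))
  dims <- readBin(con, "integer", 2L, size = 4L, endian = "little")
  meta <- readBin(con, "double", 3L, size = 8L, endian = "little")
  id_len <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  sample_id <- rawToChar(readBin(con, "raw", id_len))
  n <- dims[1] * dims[2]
  payload <- readBin(con, "integer", n + 1L, size = 2L, endian = "little",
                     signed = TRUE)
  if (length(payload) < n) stop("truncated RF payload")
  if (length(payload) > n) stop("RF payload longer than header declares")
  samples <- matrix(payload, nrow = dims[1], ncol = dims[2], byrow = TRUE)
  rf_frame(samples, sample_rate_hz = meta[1], center_freq_hz = meta[2],
           sample_id = sample_id, temperature_c = meta[3])
}
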