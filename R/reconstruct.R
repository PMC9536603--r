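# B-mode reconstruction from RF frames: blockwise-max envelope detection,
# log compression, threshold + 0-255 mapping, median filtering.

#' Reconstruction configuration
#'
#' @param depth_points_used RF samples kept per line before envelope
#'   detection (default 2048, the first half of a 4096-sample line).
#' @param decimation block length of the envelope maximum (default 4, so
#'   2048 points collapse to 512 image rows).
#' @param threshold envelope threshold on the log-compressed scale;
#'   values below it are suppressed (default 0, i.e. no suppression).
#' @param subthreshold_value value assigned below the threshold: 0
#'   (suppression, the default) or 1 (compatibility with hardware that
#'   floors dark pixels at 1).
#' @param median_kernel odd side length of the square median filter
#'   (default 3; 1 disables filtering).
#' @param log_eps positive offset inside the logarithm so a zero envelope
#'   maps to exactly 0 (default 1).
#' @param normalization how the log-compressed envelope is mapped to
#'   `[0, 255]`: `"frame_max"` (default) scales by the frame's own
#'   maximum, so every nonzero frame attains 255 somewhere — the right
#'   choice for displaying a single image; `"full_scale"` scales by the
#'   log-compressed full int16 ADC range, a fixed, temperature-independent
#'   mapping, so gray levels are comparable across the frames of a
#'   heating sweep (a per-frame maximum would cancel most of the
#'   echogenicity trend the sweep is meant to measure).
#' @return A `recon_config` list.
#' @export
recon_config <- function(depth_points_used = 2048L, decimation = 4L,
                         threshold = 0, subthreshold_value = 0,
                         median_kernel = 3L, log_eps = 1,
                         normalization = c("frame_max", "full_scale")) {
  normalization <- match.arg(normalization)
  depth_points_used <- as.integer(depth_points_used)
  decimation <- as.integer(decimation)
  median_kernel <- as.integer(median_kernel)
  if (depth_points_used %% decimation != 0L)
    stop("depth_points_used must be divisible by decimation")
  if (median_kernel < 1L || median_kernel %% 2L == 0L)
    stop("median_kernel must be an odd integer >= 1")
  if (log_eps <= 0) stop("log_eps must be > 0")
  if (threshold < 0) stop("threshold must be >= 0")
  if (!subthreshold_value %in% c(0, 1))
    stop("subthreshold_value must be 0 or 1")
  structure(list(depth_points_used = depth_points_used,
                 decimation = decimation,
                 threshold = threshold,
                 subthreshold_value = subthreshold_value,
                 median_kernel = median_kernel,
                 log_eps = log_eps,
                 normalization = normalization),
            class = "recon_config")
}

#' Envelope detection by blockwise maxima of rectified RF
#'
#' Keeps the first `depth_points_used` samples of each line, rectifies
#' (absolute value), and takes the maximum over each contiguous
#' non-overlapping block of `decimation` samples. With the defaults a
#' 128 x 4096 frame yields a 512 x 128 envelope (depth x line).
#'
#' @param frame an [rf_frame()].
#' @param config a [recon_config()].
#' @return An `envelope_image`: list with `values` (matrix, depth x line)
#'   and `b_max` (its maximum).
#' @export
detect_envelope <- function(frame, config = recon_config()) {
  depth <- config$depth_points_used
  dec <- config$decimation
  if (depth > ncol(frame$samples))
    stop("depth_points_used exceeds samples per line")
  a <- abs(t(frame$samples[, seq_len(depth), drop = FALSE])) # depth x lines
  n_out <- depth %/% dec
  env <- a[seq(1L, depth, by = dec), , drop = FALSE]
  if (dec > 1L)
    for (k in 2:dec) env <- pmax(env, a[seq(k, depth, by = dec), , drop = FALSE])
  structure(list(values = env, b_max = max(env)), class = "envelope_image")
}

#' Log-compress an envelope image
#'
#' Elementwise `v -> log10(v + log_eps) - log10(log_eps)`: nonnegative,
#' strictly increasing, and exactly 0 at v = 0.
#'
#' @param env an `envelope_image`.
#' @param config a [recon_config()].
#' @return An `envelope_image` on the compressed scale.
#' @export
log_compress <- function(env, config = recon_config()) {
  eps <- config$log_eps
  v <- log10(env$values + eps) - log10(eps)
  structure(list(values = v, b_max = max(v)), class = "envelope_image")
}

#' Threshold and map a log-compressed envelope to 8 bits
#'
#' Values below the threshold are replaced by `subthreshold_value`; the
#' rest are mapped by `pixel = min(floor(256 * b / b_ref), 255)`. With
#' `normalization = "frame_max"` the reference `b_ref` is the frame's own
#' maximum, so the frame maximum always reaches 255 and an all-zero
#' envelope maps to an all-zero image; with `"full_scale"` it is the
#' log-compressed full int16 range, fixed across frames.
#'
#' @param env a log-compressed `envelope_image`.
#' @param config a [recon_config()].
#' @param sample_id,temperature_c provenance carried into the image.
#' @return A [bmode_image()].
#' @export
threshold_and_map <- function(env, config = recon_config(),
                              sample_id = NA_character_,
                              temperature_c = NA_real_) {
  v <- env$values
  b_ref <- if (config$normalization == "full_scale")
    log10(32767 + config$log_eps) - log10(config$log_eps)
  else env$b_max
  if (b_ref <= 0) {
    px <- matrix(0L, nrow(v), ncol(v))
  } else {
    v[v < config$threshold] <- config$subthreshold_value
    px <- pmin(floor(v / b_ref * 256), 255)
  }
  bmode_image(matrix(as.integer(px), nrow(v), ncol(v)),
              sample_id = sample_id, temperature_c = temperature_c,
              params = unclass(config))
}

#' Median-filter an 8-bit image
#'
#' Square kernel of odd side `median_kernel`, borders handled by edge
#' replication; kernel 1 is the identity. Implemented as a vectorised
#' odd-even transposition sort over the kernel's shifted copies, so whole
#' frames filter in milliseconds.
#'
#' @param image a [bmode_image()].
#' @param config a [recon_config()].
#' @return A filtered [bmode_image()].
#' @export
median_filter_image <- function(image, config = recon_config()) {
  k <- config$median_kernel
  if (k == 1L) return(image)
  px <- image$pixels
  r <- (k - 1L) %/% 2L
  nr <- nrow(px); nc <- ncol(px)
  ridx <- pmin(pmax(seq_len(nr + 2L * r) - r, 1L), nr)
  cidx <- pmin(pmax(seq_len(nc + 2L * r) - r, 1L), nc)
  pad <- px[ridx, cidx, drop = FALSE]
  shifts <- vector("list", k * k)
  t <- 0L
  for (di in 0:(k - 1L)) for (dj in 0:(k - 1L)) {
    t <- t + 1L
    shifts[[t]] <- pad[di + seq_len(nr), dj + seq_len(nc), drop = FALSE]
  }
  m <- length(shifts)
  for (pass in seq_len(m)) {
    start <- if (pass %% 2L == 1L) 1L else 2L
    i <- start
    while (i + 1L <= m) {
      lo <- pmin(shifts[[i]], shifts[[i + 1L]])
      hi <- pmax(shifts[[i]], shifts[[i + 1L]])
      shifts[[i]] <- lo; shifts[[i + 1L]] <- hi
      i <- i + 2L
    }
  }
  med <- shifts[[(m + 1L) %/% 2L]]
  bmode_image(matrix(as.integer(med), nr, nc), sample_id = image$sample_id,
              temperature_c = image$temperature_c, params = image$params)
}

#' Reconstruct a B-mode image from an RF frame
#'
#' The full chain: envelope detection, log compression, threshold +
#' 8-bit mapping, median filter. Deterministic.
#'
#' @param frame an [rf_frame()].
#' @param config a [recon_config()].
#' @return A [bmode_image()] of shape
#'   `(depth_points_used / decimation) x n_lines`.
#' @export
reconstruct_bmode <- function(frame, config = recon_config()) {
  env <- detect_envelope(frame, config)
  env <- log_compress(env, config)
  img <- threshold_and_map(env, config, sample_id = frame$sample_id,
                           temperature_c = frame$temperature_c)
  median_filter_image(img, config)
}
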