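# B-mode image container and 8-bit grayscale TIFF export.

#' Construct a B-mode image
#'
#' An 8-bit brightness-mode image. The first axis is depth (image rows),
#' the second is the scan line (columns); indices are 0-based in all
#' user-facing coordinates.
#'
#' @param pixels integer matrix in `[0, 255]`, `n_rows x n_cols`.
#' @param sample_id,temperature_c provenance of the source RF frame.
#' @param params reconstruction parameters used (list), kept as provenance.
#' @return An object of class `bmode_image`.
#' @export
bmode_image <- function(pixels, sample_id = NA_character_,
                        temperature_c = NA_real_, params = list()) {
  if (!is.matrix(pixels)) stop("`pixels` must be a matrix")
  storage.mode(pixels) <- "integer"
  if (anyNA(pixels) || min(pixels) < 0L || max(pixels) > 255L)
    stop("pixel values must lie in [0, 255]")
  structure(list(pixels = pixels, sample_id = sample_id,
                 temperature_c = temperature_c, params = params),
            class = "bmode_image")
}

#' @export
print.bmode_image <- function(x, ...) {
  cat(sprintf("<bmode_image> %d x %d, gray range [%d, %d]\n",
              nrow(x$pixels), ncol(x$pixels), min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' Write a B-mode image as 8-bit grayscale TIFF
#'
#' Values survive a write/read cycle unchanged (uncompressed 8-bit
#' storage).
#'
#' @param image a [bmode_image()].
#' @param path destination `.tif` path.
#' @return `path`, invisibly.
#' @export
write_bmode_tiff <- function(image, path) {
  tiff::writeTIFF(image$pixels / 255, path, bits.per.sample = 8L,
                  compression = "none")
  invisible(path)
}

#' Read an 8-bit grayscale TIFF as a B-mode image
#'
#' @param path TIFF path.
#' @return A [bmode_image()].
#' @export
read_bmode_tiff <- function(path) {
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  bmode_image(matrix(as.integer(round(m * 255)), nrow(m), ncol(m)))
}
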