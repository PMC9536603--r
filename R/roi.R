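# Region-of-interest selection and extraction.

#' Construct an ROI patch
#'
#' @param pixels integer matrix in `[0, 255]`, square (default 16 x 16).
#' @param origin 0-based `(row, col)` of the patch's top-left corner in
#'   the source image (row = depth index).
#' @return An object of class `roi_patch`.
#' @export
roi_patch <- function(pixels, origin = c(0L, 0L)) {
  if (!is.matrix(pixels)) stop("`pixels` must be a matrix")
  storage.mode(pixels) <- "integer"
  if (min(pixels) < 0L || max(pixels) > 255L)
    stop("ROI pixel values must lie in [0, 255]")
  structure(list(pixels = pixels, origin = as.integer(origin)),
            class = "roi_patch")
}

#' Select random ROIs within a B-mode image
#'
#' Seeded uniform placement of axis-aligned square patches fully inside
#' the image, excluding a margin (near-field rows at the top and the
#' lateral edges, where reconstruction artifacts concentrate). Placement
#' depends only on the seed and the image dimensions, so the same seed
#' tracks the same tissue locations across a temperature sweep.
#'
#' @param image a [bmode_image()].
#' @param n_rois number of patches.
#' @param size patch side length (default 16).
#' @param seed integer seed for placement.
#' @param margin either one number (all four sides) or a length-4 vector
#'   `(top, bottom, left, right)`; default `c(32, 0, 8, 8)`.
#' @return List of [roi_patch()] objects.
#' @export
select_rois <- function(image, n_rois, size = 16L, seed = 1L,
                        margin = c(32L, 0L, 8L, 8L)) {
  if (length(margin) == 1L) margin <- rep(as.integer(margin), 4L)
  if (length(margin) != 4L) stop("margin must have length 1 or 4")
  nr <- nrow(image$pixels); nc <- ncol(image$pixels)
  row_min <- margin[1]; row_max <- nr - size - margin[2]      # 0-based origins
  col_min <- margin[3]; col_max <- nc - size - margin[4]
  if (row_max < row_min || col_max < col_min)
    stop("image too small for the requested ROI size and margin")
  if (n_rois == 0L) return(list())
  origins <- with_seed(seed, cbind(
    row = sample(row_min:row_max, n_rois, replace = TRUE),
    col = sample(col_min:col_max, n_rois, replace = TRUE)))
  lapply(seq_len(n_rois), function(i)
    extract_roi(image, origins[i, "row"], origins[i, "col"], size))
}

#' Extract one ROI at an explicit origin
#'
#' @param image a [bmode_image()].
#' @param row,col 0-based top-left corner (row = depth index).
#' @param size patch side length.
#' @return A [roi_patch()].
#' @export
extract_roi <- function(image, row, col, size = 16L) {
  nr <- nrow(image$pixels); nc <- ncol(image$pixels)
  if (row < 0 || col < 0 || row + size > nr || col + size > nc)
    stop("ROI extends outside the image")
  roi_patch(image$pixels[row + seq_len(size), col + seq_len(size),
                         drop = FALSE],
            origin = c(row, col))
}
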