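# First-order (gray-level histogram) texture statistics.

#' Gray-level histogram features of an ROI
#'
#' Mean gray scale, population variance (reported downstream as its
#' square root, the standard deviation), and Shannon entropy of the
#' 256-level histogram in bits (`-sum p_i log2 p_i`, with
#' `0 * log 0 := 0`). For an 8-bit patch the entropy lies in `[0, 8]`
#' bits and is bounded by `log2` of the number of distinct levels
#' present.
#'
#' @param roi a [roi_patch()] or an integer matrix in `[0, 255]`.
#' @return List with `mean_gray_scale`, `variance`, `std`, `entropy`.
#' @export
glh_features <- function(roi) {
  px <- roi_pixels(roi)
  n <- length(px)
  if (n == 0L) stop("empty ROI")
  m <- mean(px)
  v <- sum((px - m)^2) / n
  p <- tabulate(px + 1L, nbins = 256L) / n
  p <- p[p > 0]
  list(mean_gray_scale = m,
       variance = v,
       std = sqrt(v),
       entropy = -sum(p * log2(p)))
}

roi_pixels <- function(roi) {
  px <- if (inherits(roi, "roi_patch")) roi$pixels else roi
  if (!is.matrix(px)) stop("expected an roi_patch or a matrix")
  storage.mode(px) <- "integer"
  px
}
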