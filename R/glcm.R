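# Gray-level co-occurrence matrices and the four Haralick-style features
# computed from them (contrast, correlation, energy, homogeneity).

#' GLCM configuration
#'
#' @param levels number of gray levels L after quantization (default 16,
#'   the standard reduction of 8-bit images for texture work).
#' @param distance pixel pair offset d (default 1).
#' @param angles directions in degrees, subset of `c(0, 45, 90, 135)`.
#' @param symmetric count each pair in both orders (Haralick's
#'   convention; default TRUE).
#' @return A `glcm_config` list.
#' @export
glcm_config <- function(levels = 16L, distance = 1L,
                        angles = c(0, 45, 90, 135), symmetric = TRUE) {
  levels <- as.integer(levels); distance <- as.integer(distance)
  if (levels < 2L) stop("levels must be >= 2")
  if (distance < 1L) stop("distance must be >= 1")
  if (length(angles) == 0L || !all(angles %in% c(0, 45, 90, 135)))
    stop("angles must be a non-empty subset of {0, 45, 90, 135}")
  structure(list(levels = levels, distance = distance, angles = angles,
                 symmetric = isTRUE(symmetric)),
            class = "glcm_config")
}

#' Quantize an 8-bit patch to L gray levels
#'
#' Uniform binning: `level = floor(pixel * L / 256)`, so 0 maps to 0 and
#' 255 maps to L - 1; L = 256 is the identity.
#'
#' @param patch a [roi_patch()] or integer matrix in `[0, 255]`.
#' @param levels number of levels L.
#' @return Integer matrix with values in `[0, L - 1]`.
#' @export
quantize_levels <- function(patch, levels = 16L) {
  px <- roi_pixels(patch)
  matrix(as.integer(floor(px * as.numeric(levels) / 256)),
         nrow(px), ncol(px))
}

# (row, col) offset of each direction, row index increasing downward
glcm_offset <- function(angle, d) {
  switch(as.character(angle),
         "0"   = c(0L, d),
         "45"  = c(-d, d),
         "90"  = c(-d, 0L),
         "135" = c(-d, -d),
         stop("unsupported angle: ", angle))
}

#' Gray-level co-occurrence matrix of a quantized patch
#'
#' Counts all in-bounds ordered pixel pairs separated by the direction's
#' offset; with `symmetric = TRUE` the transposed pairs are added. The
#' counts are normalized by the total pair count so the entries sum to 1.
#'
#' @param patch integer matrix already quantized to `[0, levels - 1]`.
#' @param angle one of 0, 45, 90, 135 (degrees).
#' @param config a [glcm_config()].
#' @return A `glcm_matrix`: list with `probabilities` (L x L), `angle`,
#'   `distance`, `pair_count`.
#' @export
glcm_matrix <- function(patch, angle, config = glcm_config()) {
  if (!angle %in% config$angles) stop("angle not enabled in config")
  L <- config$levels
  if (min(patch) < 0L || max(patch) >= L)
    stop("patch is not quantized to [0, levels - 1]")
  off <- glcm_offset(angle, config$distance)
  nr <- nrow(patch); nc <- ncol(patch)
  rows <- seq_len(nr); cols <- seq_len(nc)
  rows_a <- rows[rows + off[1] >= 1L & rows + off[1] <= nr]
  cols_a <- cols[cols + off[2] >= 1L & cols + off[2] <= nc]
  if (length(rows_a) == 0L || length(cols_a) == 0L)
    stop("patch too small for the requested offset")
  a <- patch[rows_a, cols_a, drop = FALSE]
  b <- patch[rows_a + off[1], cols_a + off[2], drop = FALSE]
  counts <- tabulate(a * L + b + 1L, nbins = L * L)
  if (config$symmetric) counts <- counts + tabulate(b * L + a + 1L, nbins = L * L)
  pair_count <- sum(counts)
  probs <- matrix(counts / pair_count, L, L, byrow = TRUE) # row i, col j
  structure(list(probabilities = probs, angle = angle,
                 distance = config$distance, pair_count = pair_count),
            class = "glcm_matrix")
}

#' Haralick-style features of a normalized GLCM
#'
#' With `P(i, j)` the normalized matrix and marginal means/SDs `mu_x`,
#' `mu_y`, `sigma_x`, `sigma_y` taken over the row and column sums:
#' contrast `sum (i - j)^2 P`, correlation
#' `sum (i - mu_x)(j - mu_y) P / (sigma_x sigma_y)` (0 when a marginal is
#' degenerate), energy `sum P^2`, homogeneity `sum P / (1 + (i - j)^2)`.
#'
#' @param m a `glcm_matrix`.
#' @return List with `contrast`, `correlation`, `energy`, `homogeneity`.
#' @export
glcm_features <- function(m) {
  P <- m$probabilities
  L <- nrow(P)
  i <- matrix(0:(L - 1L), L, L)        # row index
  j <- t(i)                            # column index
  px <- rowSums(P); py <- colSums(P)
  lev <- 0:(L - 1L)
  mu_x <- sum(lev * px); mu_y <- sum(lev * py)
  sd_x <- sqrt(sum((lev - mu_x)^2 * px))
  sd_y <- sqrt(sum((lev - mu_y)^2 * py))
  corr <- if (sd_x * sd_y > 0)
    sum((i - mu_x) * (j - mu_y) * P) / (sd_x * sd_y) else 0
  list(contrast = sum((i - j)^2 * P),
       correlation = corr,
       energy = sum(P^2),
       homogeneity = sum(P / (1 + (i - j)^2)))
}
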