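# Gray level-gradient co-occurrence matrix: the joint histogram of
# quantized gray level and quantized gradient magnitude per pixel, and
# the twelve second-order statistics computed from it.

#' GGCM configuration
#'
#' @param gray_levels Lg gray quantization levels (default 16).
#' @param gradient_levels Ls gradient quantization levels (default 16).
#' @param gradient_operator `"sobel"` (default) or
#'   `"central-difference"`.
#' @return A `ggcm_config` list.
#' @export
ggcm_config <- function(gray_levels = 16L, gradient_levels = 16L,
                        gradient_operator = c("sobel", "central-difference")) {
  gray_levels <- as.integer(gray_levels)
  gradient_levels <- as.integer(gradient_levels)
  if (gray_levels < 2L || gradient_levels < 2L)
    stop("gray_levels and gradient_levels must be >= 2")
  structure(list(gray_levels = gray_levels,
                 gradient_levels = gradient_levels,
                 gradient_operator = match.arg(gradient_operator)),
            class = "ggcm_config")
}

# edge-replicated pad by one pixel
pad_replicate1 <- function(px) {
  nr <- nrow(px); nc <- ncol(px)
  px[pmin(pmax(0:(nr + 1L), 1L), nr), pmin(pmax(0:(nc + 1L), 1L), nc),
     drop = FALSE]
}

#' Gradient magnitude image of an 8-bit patch
#'
#' Sobel 3x3 (default) or central-difference magnitude
#' `sqrt(gx^2 + gy^2)` with edge-replicated borders. A constant patch
#' has zero gradient everywhere.
#'
#' @param patch a [roi_patch()] or integer matrix in `[0, 255]`.
#' @param config a [ggcm_config()].
#' @return Nonnegative numeric matrix, same shape as the patch.
#' @export
gradient_image <- function(patch, config = ggcm_config()) {
  px <- roi_pixels(patch)
  nr <- nrow(px); nc <- ncol(px)
  p <- pad_replicate1(px)
  s <- function(di, dj) p[di + seq_len(nr) + 1L, dj + seq_len(nc) + 1L,
                          drop = FALSE]
  if (config$gradient_operator == "sobel") {
    gx <- (s(-1, 1) + 2 * s(0, 1) + s(1, 1)) -
          (s(-1, -1) + 2 * s(0, -1) + s(1, -1))
    gy <- (s(1, -1) + 2 * s(1, 0) + s(1, 1)) -
          (s(-1, -1) + 2 * s(-1, 0) + s(-1, 1))
  } else {
    gx <- (s(0, 1) - s(0, -1)) / 2
    gy <- (s(1, 0) - s(-1, 0)) / 2
  }
  sqrt(gx^2 + gy^2)
}

#' Gray level-gradient co-occurrence matrix of a patch
#'
#' Gray values are quantized to `Lg` levels with [quantize_levels()];
#' gradient magnitudes are rescaled linearly so the patch maximum maps to
#' `Ls - 1` (an all-zero gradient maps to level 0) and rounded half-up.
#' `H(i, j)` counts pixels with gray level i and gradient level j; each
#' pixel is counted exactly once, so the counts sum to the pixel count.
#'
#' @param patch a [roi_patch()] or integer matrix in `[0, 255]`.
#' @param config a [ggcm_config()].
#' @return A `ggcm_matrix`: list with integer `counts` (Lg x Ls),
#'   `probabilities`, and the two level counts.
#' @export
ggcm_matrix <- function(patch, config = ggcm_config()) {
  px <- roi_pixels(patch)
  Lg <- config$gray_levels; Ls <- config$gradient_levels
  gray <- quantize_levels(px, Lg)
  gmag <- gradient_image(px, config)
  gmax <- max(gmag)
  grad <- if (gmax > 0)
    matrix(as.integer(floor(gmag / gmax * (Ls - 1L) + 0.5)),
           nrow(px), ncol(px))
  else matrix(0L, nrow(px), ncol(px))
  counts <- tabulate(gray * Ls + grad + 1L, nbins = Lg * Ls)
  H <- matrix(counts, Lg, Ls, byrow = TRUE)   # row i = gray, col j = gradient
  structure(list(counts = H, probabilities = H / sum(H),
                 gray_levels = Lg, gradient_levels = Ls),
            class = "ggcm_matrix")
}

#' The twelve GGCM texture statistics
#'
#' With `H` the count matrix, `T = sum(H)`, `p = H / T`, row/column sums
#' `H_i.`, `H_.j`, marginals `p_i.`, `p_.j` and their means/SDs:
#' small-gradient preponderance `[sum_j H_.j / (1 + j)^2] / T`;
#' large-gradient preponderance `[sum_j H_.j j^2] / T`; gray-level
#' nonuniformity `[sum_i H_i.^2] / T`; gradient nonuniformity
#' `[sum_j H_.j^2] / T`; energy `sum p^2`; mean gradient `mu_j`;
#' gradient mean square deviation `sigma_j`; correlation
#' `sum (i - mu_i)(j - mu_j) p / (sigma_i sigma_j)` (0 when degenerate);
#' gradient entropy `-sum_j p_.j log2 p_.j`; hybrid entropy
#' `-sum p log2 p`; inertia `sum (i - j)^2 p`; inverse difference moment
#' `sum p / (1 + (i - j)^2)`. Indices are 0-based; `0 log 0 := 0`.
#'
#' @param g a `ggcm_matrix`.
#' @return Named list of the 12 statistics.
#' @export
ggcm_features <- function(g) {
  H <- g$counts
  total <- sum(H)
  if (total == 0) stop("empty GGCM")
  p <- H / total
  Lg <- nrow(H); Ls <- ncol(H)
  i <- matrix(0:(Lg - 1L), Lg, Ls)
  j <- matrix(0:(Ls - 1L), Lg, Ls, byrow = TRUE)
  Hi <- rowSums(H); Hj <- colSums(H)
  pi_ <- Hi / total; pj_ <- Hj / total
  iv <- 0:(Lg - 1L); jv <- 0:(Ls - 1L)
  mu_i <- sum(iv * pi_); mu_j <- sum(jv * pj_)
  sd_i <- sqrt(sum((iv - mu_i)^2 * pi_))
  sd_j <- sqrt(sum((jv - mu_j)^2 * pj_))
  ent <- function(q) { q <- q[q > 0]; -sum(q * log2(q)) }
  corr <- if (sd_i * sd_j > 0)
    sum((i - mu_i) * (j - mu_j) * p) / (sd_i * sd_j) else 0
  list(small_gradient = sum(Hj / (1 + jv)^2) / total,
       large_gradient = sum(Hj * jv^2) / total,
       gray_nonuniformity = sum(Hi^2) / total,
       gradient_nonuniformity = sum(Hj^2) / total,
       energy = sum(p^2),
       mean_gradient = mu_j,
       gradient_msd = sd_j,
       correlation = corr,
       gradient_entropy = ent(pj_),
       hybrid_entropy = ent(as.vector(p)),
       inertia = sum((i - j)^2 * p),
       inverse_difference = sum(p / (1 + (i - j)^2)))
}
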