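# Assembly of the full 31-feature texture vector of one ROI.

#' The 31 stable feature names
#'
#' 3 first-order (histogram) features, 4 co-occurrence features at each
#' of 4 directions, and 12 gray-gradient statistics, in a fixed order.
#'
#' @param angles GLCM directions (default `c(0, 45, 90, 135)`).
#' @return Character vector of feature names.
#' @export
feature_names <- function(angles = c(0, 45, 90, 135)) {
  glh <- paste0("glh.", c("mean_gray_scale", "std", "entropy"))
  glcm <- as.vector(t(outer(angles,
                            c("contrast", "correlation", "energy", "homogeneity"),
                            function(a, f) paste0("glcm.", f, ".", a))))
  ggcm <- paste0("ggcm.", c("small_gradient", "large_gradient",
                            "gray_nonuniformity", "gradient_nonuniformity",
                            "energy", "mean_gradient", "gradient_msd",
                            "correlation", "gradient_entropy",
                            "hybrid_entropy", "inertia",
                            "inverse_difference"))
  c(glh, glcm, ggcm)
}

#' Extract the full texture feature vector of one ROI
#'
#' First-order features are computed on the raw 8-bit patch; GLCM
#' features on the patch quantized to `glcm_cfg$levels`, one set per
#' direction; GGCM features per `ggcm_cfg`. Deterministic.
#'
#' @param roi a [roi_patch()] or integer matrix in `[0, 255]`.
#' @param glcm_cfg a [glcm_config()].
#' @param ggcm_cfg a [ggcm_config()].
#' @return Named numeric vector of length 31 (see [feature_names()]).
#' @export
extract_features <- function(roi, glcm_cfg = glcm_config(),
                             ggcm_cfg = ggcm_config()) {
  px <- roi_pixels(roi)
  glh <- glh_features(px)
  out <- c(glh.mean_gray_scale = glh$mean_gray_scale,
           glh.std = glh$std,
           glh.entropy = glh$entropy)
  q <- quantize_levels(px, glcm_cfg$levels)
  for (a in glcm_cfg$angles) {
    f <- glcm_features(glcm_matrix(q, a, glcm_cfg))
    v <- c(f$contrast, f$correlation, f$energy, f$homogeneity)
    names(v) <- paste0("glcm.",
                       c("contrast", "correlation", "energy", "homogeneity"),
                       ".", a)
    out <- c(out, v)
  }
  gg <- ggcm_features(ggcm_matrix(px, ggcm_cfg))
  ggv <- unlist(gg)
  names(ggv) <- paste0("ggcm.", names(gg))
  out <- c(out, ggv)
  stopifnot(all(is.finite(out)))
  out[feature_names(glcm_cfg$angles)]
}

#' Average texture features over the ROIs of one image
#'
#' @param image a [bmode_image()].
#' @param rois list of [roi_patch()] (e.g. from [select_rois()]).
#' @param glcm_cfg,ggcm_cfg feature configurations.
#' @return Named numeric vector of length 31: per-feature mean over ROIs.
#' @export
image_features <- function(image, rois, glcm_cfg = glcm_config(),
                           ggcm_cfg = ggcm_config()) {
  if (length(rois) == 0L) stop("no ROIs supplied")
  mats <- vapply(rois, extract_features, numeric(length(feature_names())),
                 glcm_cfg = glcm_cfg, ggcm_cfg = ggcm_cfg)
  rowMeans(mats)
}
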