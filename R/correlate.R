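# Temperature correlation of texture features: per-sample Pearson
# coefficients, aggregation across samples, linear trend fits, ranking.

#' Pearson correlation with a two-sided p-value
#'
#' Product-moment correlation with the exact t-transform p-value
#' (n - 2 degrees of freedom). A degenerate input (zero variance in
#' either vector) yields `r = 0`, `p = 1` with `degenerate = TRUE`
#' instead of failing, so batch runs over many features stay total.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return List with `r`, `p`, `degenerate`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r = 0, p = 1, degenerate = TRUE))
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, degenerate = FALSE)
}

#' Build per-sample series from a feature table
#'
#' @param features data.frame from the extraction stage: `sample_id`,
#'   `temperature_c`, and the 31 feature columns.
#' @return Named list of `sample_series`: each holds `sample_id`, the
#'   sorted `temperatures`, and the `|temperatures| x 31` feature matrix.
#' @export
build_sample_series <- function(features) {
  fn <- intersect(feature_names(), names(features))
  if (length(fn) == 0L) stop("no recognised feature columns")
  lapply(split(features, features$sample_id), function(df) {
    df <- df[order(df$temperature_c), , drop = FALSE]
    m <- as.matrix(df[fn])
    if (anyNA(m)) stop("missing feature values in sample ", df$sample_id[1])
    structure(list(sample_id = df$sample_id[1],
                   temperatures = df$temperature_c,
                   features = m),
              class = "sample_series")
  })
}

#' Per-sample correlation of every feature with temperature
#'
#' @param series a `sample_series` (see [build_sample_series()]).
#' @return data.frame with one row per feature: `feature`, `r`, `p`,
#'   `degenerate`.
#' @export
per_sample_correlations <- function(series) {
  res <- lapply(colnames(series$features), function(fn) {
    pr <- pearson_r(series$temperatures, series$features[, fn])
    data.frame(feature = fn, r = pr$r, p = pr$p,
               degenerate = pr$degenerate)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Aggregate per-sample correlations across samples
#'
#' For each feature: mean and sample standard deviation (n - 1
#' denominator) of the per-sample r values, the mean two-sided p-value,
#' a Bonferroni-adjusted copy of it (transparency only, not used for
#' ranking), and the least-squares slope of the across-sample mean
#' feature curve against temperature.
#'
#' @param all_series list of `sample_series` sharing one temperature
#'   grid and feature set.
#' @return A `correlation_summary` data.frame with one row per feature:
#'   `feature`, `r_mean`, `r_std`, `p_mean`, `p_bonferroni`,
#'   `slope_mean`, `n_samples`.
#' @export
aggregate_across_samples <- function(all_series) {
  if (length(all_series) < 2L) stop("need at least 2 samples")
  fn <- colnames(all_series[[1]]$features)
  temps <- all_series[[1]]$temperatures
  for (s in all_series) {
    if (!identical(colnames(s$features), fn))
      stop("inconsistent feature sets across samples")
    if (!isTRUE(all.equal(s$temperatures, temps)))
      stop("samples do not share a temperature grid")
  }
  per <- lapply(all_series, per_sample_correlations)
  r_mat <- matrix(vapply(per, function(d) d$r, numeric(length(fn))),
                  nrow = length(fn))
  p_mat <- matrix(vapply(per, function(d) d$p, numeric(length(fn))),
                  nrow = length(fn))
  mean_curves <- mean_feature_curves(all_series)
  slopes <- vapply(fn, function(f)
    unname(stats::coef(stats::lm(mean_curves[, f] ~ temps))[2]), 0)
  out <- data.frame(feature = fn,
                    r_mean = rowMeans(r_mat),
                    r_std = apply(r_mat, 1, stats::sd),
                    p_mean = rowMeans(p_mat),
                    p_bonferroni = pmin(1, rowMeans(p_mat) * length(fn)),
                    slope_mean = slopes,
                    n_samples = length(all_series))
  rownames(out) <- NULL
  class(out) <- c("correlation_summary", "data.frame")
  out
}

#' Across-sample mean feature curves
#'
#' @param all_series list of `sample_series` on one temperature grid.
#' @return Matrix `|temperatures| x n_features` of across-sample means,
#'   with the temperature grid as the `temperatures` attribute.
#' @export
mean_feature_curves <- function(all_series) {
  acc <- Reduce(`+`, lapply(all_series, function(s) s$features))
  m <- acc / length(all_series)
  attr(m, "temperatures") <- all_series[[1]]$temperatures
  m
}

#' Least-squares slopes of a mean curve below and above a breakpoint
#'
#' Used to detect the coagulation plateau: the slope of a feature's mean
#' curve over temperatures above the breakpoint should be smaller than
#' over those below it.
#'
#' @param curve numeric vector of mean feature values.
#' @param temperatures matching degC grid.
#' @param breakpoint degC breakpoint (default 54, in vitro liver
#'   coagulation).
#' @return List with `slope_below` and `slope_above` (degC^-1).
#' @export
segment_slopes <- function(curve, temperatures, breakpoint = 54) {
  lo <- temperatures <= breakpoint
  hi <- temperatures >= breakpoint
  fit <- function(sel) {
    if (sum(sel) < 2L) stop("fewer than 2 points on one side of the breakpoint")
    unname(stats::coef(stats::lm(curve[sel] ~ temperatures[sel]))[2])
  }
  list(slope_below = fit(lo), slope_above = fit(hi))
}

#' Rank features by the magnitude of their mean correlation
#'
#' Sorted by `|r_mean|` descending; ties broken by smaller `r_std`, then
#' feature name.
#'
#' @param summary a `correlation_summary`.
#' @param k how many features to return (default all).
#' @return The top-k rows of the summary in rank order.
#' @export
rank_features <- function(summary, k = nrow(summary)) {
  if (k > nrow(summary)) stop("k exceeds the number of features")
  ord <- order(-abs(summary$r_mean), summary$r_std, summary$feature)
  out <- summary[ord, , drop = FALSE][seq_len(k), , drop = FALSE]
  rownames(out) <- NULL
  out
}
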