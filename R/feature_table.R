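# Tidy on-disk feature tables: one row per (sample, temperature), one
# column per texture feature. Numeric cells are written with 17
# significant digits so a write/read cycle is lossless for doubles.

#' Write a feature table to CSV
#'
#' @param features data.frame with columns `sample_id`, `temperature_c`
#'   and the 31 texture feature columns (see [feature_names()]).
#' @param path destination CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(features, path) {
  stopifnot(is.data.frame(features))
  need <- c("sample_id", "temperature_c")
  if (!all(need %in% names(features)))
    stop("feature table needs sample_id and temperature_c columns")
  out <- data.table::as.data.table(features)
  num <- names(out)[vapply(out, is.numeric, TRUE)]
  for (cn in num) data.table::set(out, j = cn,
                                  value = sprintf("%.17g", out[[cn]]))
  data.table::fwrite(out, path)
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#'
#' @param path CSV path.
#' @return A data.frame.
#' @export
read_feature_table <- function(path) {
  df <- as.data.frame(data.table::fread(path))
  for (cn in setdiff(names(df), "sample_id"))
    df[[cn]] <- as.numeric(df[[cn]])
  df
}
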