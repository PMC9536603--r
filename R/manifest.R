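# Dataset manifests: which RF frame file belongs to which (sample,
# temperature) pair.

#' Load a dataset manifest
#'
#' A manifest is a CSV with header `sample_id,temperature_c,frame_path`,
#' one row per acquired frame. Relative `frame_path` entries are resolved
#' against the manifest's own directory. Duplicate (sample, temperature)
#' pairs (temperatures compared with 1e-6 degC tolerance) are an error;
#' a ragged temperature grid (samples not all covering the same
#' temperatures) only warns.
#'
#' @param path manifest CSV path.
#' @param check_paths verify that every `frame_path` exists (default TRUE).
#' @return A `dataset_manifest`: list with `entries` (data.frame),
#'   `n_samples`, and the sorted unique `temperatures`.
#' @export
load_manifest <- function(path, check_paths = TRUE) {
  entries <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("sample_id", "temperature_c", "frame_path")
  missing <- setdiff(required, names(entries))
  if (length(missing))
    stop("manifest is missing column(s): ", paste(missing, collapse = ", "))
  entries <- entries[required]
  entries$temperature_c <- suppressWarnings(as.numeric(entries$temperature_c))
  if (anyNA(entries$temperature_c))
    stop("manifest contains unparsable temperature values")
  # dedup key on a 1e-6 degC grid
  key <- paste(entries$sample_id, round(entries$temperature_c * 1e6))
  if (anyDuplicated(key))
    stop("duplicate (sample_id, temperature_c) pair(s) in manifest: ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  base_dir <- dirname(normalizePath(path, mustWork = FALSE))
  resolved <- ifelse(grepl("^(/|[A-Za-z]:)", entries$frame_path),
                     entries$frame_path,
                     file.path(base_dir, entries$frame_path))
  if (check_paths && nrow(entries) > 0) {
    bad <- !file.exists(resolved)
    if (any(bad))
      stop("manifest frame_path(s) not found: ",
           paste(utils::head(resolved[bad], 3), collapse = ", "))
  }
  entries$frame_path <- resolved
  entries <- entries[order(entries$sample_id, entries$temperature_c), ,
                     drop = FALSE]
  rownames(entries) <- NULL
  temps <- sort(unique(entries$temperature_c))
  grids <- tapply(entries$temperature_c, entries$sample_id,
                  function(t) paste(sort(t), collapse = ","))
  if (length(grids) > 1 && length(unique(grids)) > 1)
    warning("samples do not share a common temperature grid")
  structure(list(entries = entries,
                 n_samples = length(unique(entries$sample_id)),
                 temperatures = temps),
            class = "dataset_manifest")
}

#' Write a dataset manifest CSV
#'
#' @param entries data.frame with columns `sample_id`, `temperature_c`,
#'   `frame_path`.
#' @param path destination CSV path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(entries, path) {
  utils::write.csv(entries[c("sample_id", "temperature_c", "frame_path")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.dataset_manifest <- function(x, ...) {
  cat(sprintf("<dataset_manifest> %d frames: %d samples x %d temperatures (%s degC)\n",
              nrow(x$entries), x$n_samples, length(x$temperatures),
              if (length(x$temperatures))
                paste0(min(x$temperatures), "-", max(x$temperatures)) else "-"))
  invisible(x)
}
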