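# End-to-end orchestration: simulate (or load) a heating sweep,
# reconstruct, extract ROI features, correlate with temperature.

#' Pipeline configuration
#'
#' @param synthetic a [synthetic_config()] describing the sweep to
#'   simulate, or NULL when running from an existing manifest.
#' @param reconstruction a [recon_config()]; the pipeline default uses
#'   the fixed `"full_scale"` dynamic-range mapping so gray levels are
#'   comparable across temperatures (see [recon_config()]).
#' @param glcm a [glcm_config()].
#' @param ggcm a [ggcm_config()].
#' @param rois_per_image ROIs averaged per image (default 5).
#' @param roi_seed seed for ROI placement; combined with each sample id
#'   so every sample keeps its own fixed ROI locations across the sweep.
#' @param output_dir where [run_experiment()] writes its outputs.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(synthetic = synthetic_config(),
                            reconstruction = recon_config(
                              normalization = "full_scale"),
                            glcm = glcm_config(),
                            ggcm = ggcm_config(),
                            rois_per_image = 5L,
                            roi_seed = 1L,
                            output_dir = tempfile("thermotex_run_")) {
  structure(list(synthetic = synthetic,
                 reconstruction = reconstruction,
                 glcm = glcm, ggcm = ggcm,
                 rois_per_image = as.integer(rois_per_image),
                 roi_seed = as.integer(roi_seed),
                 output_dir = output_dir),
            class = "pipeline_config")
}

# hash of the scientific configuration; the output location is excluded
# so reruns of the same experiment in different directories match
config_fingerprint <- function(config) {
  cfg <- unclass(config)
  cfg$output_dir <- NULL
  derive_seed(0L, paste(deparse(cfg), collapse = ""))
}

roi_origins_for_sample <- function(sample_id, config, image) {
  seed <- derive_seed(config$roi_seed, sample_id, "rois")
  select_rois(image, config$rois_per_image, size = 16L, seed = seed)
}

frame_feature_row <- function(frame, config) {
  img <- reconstruct_bmode(frame, config$reconstruction)
  rois <- roi_origins_for_sample(frame$sample_id, config, img)
  feats <- image_features(img, rois, config$glcm, config$ggcm)
  cbind(data.frame(sample_id = frame$sample_id,
                   temperature_c = frame$temperature_c),
        as.data.frame(as.list(feats), check.names = FALSE))
}

#' Simulate, reconstruct and extract features for a sweep, in memory
#'
#' The frame-by-frame path used by the disk pipeline, without any I/O:
#' for every (sample, temperature) of the synthetic config, simulate the
#' RF frame, reconstruct the B-mode image, and average the 31 texture
#' features over the configured ROIs. ROI placement is frozen per sample
#' so the same tissue locations are tracked across the sweep.
#'
#' @param config a [pipeline_config()] with a non-NULL `synthetic`.
#' @return Feature table: one row per (sample, temperature), 33 columns.
#' @export
compute_sweep_features <- function(config = pipeline_config()) {
  syn <- config$synthetic
  if (is.null(syn)) stop("compute_sweep_features needs a synthetic config")
  rows <- vector("list", syn$n_samples * length(syn$temperatures))
  t <- 0L
  for (sid in sweep_sample_ids(syn)) {
    for (temp in syn$temperatures) {
      t <- t + 1L
      frame <- simulate_rf_frame(sid, temp, syn)
      rows[[t]] <- frame_feature_row(frame, config)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Extract features for every frame of an on-disk manifest
#'
#' @param manifest a `dataset_manifest` (see [load_manifest()]).
#' @param config a [pipeline_config()].
#' @param images_dir optional directory; when given, each reconstructed
#'   B-mode image is also written there as 8-bit grayscale TIFF.
#' @return Feature table as in [compute_sweep_features()].
#' @export
extract_manifest_features <- function(manifest, config = pipeline_config(),
                                      images_dir = NULL) {
  if (!is.null(images_dir))
    dir.create(images_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- vector("list", nrow(manifest$entries))
  for (i in seq_len(nrow(manifest$entries))) {
    frame <- read_rf_frame(manifest$entries$frame_path[i])
    if (!is.null(images_dir)) {
      img <- reconstruct_bmode(frame, config$reconstruction)
      write_bmode_tiff(img, file.path(images_dir,
        sprintf("%s_T%05.1f.tif", frame$sample_id, frame$temperature_c)))
    }
    rows[[i]] <- frame_feature_row(frame, config)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the full experiment to disk
#'
#' Stages: (1) simulate the sweep and write RF frames plus manifest;
#' (2) reconstruct B-mode images (TIFF); (3) extract and write the
#' feature table; (4) correlate with temperature and write the summary
#' and the top-ranked features. Every stage is a pure function of the
#' config, so a rerun with the same config reproduces identical CSVs.
#'
#' @param config a [pipeline_config()].
#' @param top_k how many top features to report (default 5).
#' @return List with `manifest`, `images_dir`, `features_csv`,
#'   `summary_csv`, `top_features` (data.frame), `config_hash`.
#' @export
run_experiment <- function(config = pipeline_config(), top_k = 5L) {
  out_dir <- config$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_fingerprint(config)
  message(sprintf("[thermotex] run %d: simulating %d samples x %d temperatures",
                  hash, config$synthetic$n_samples,
                  length(config$synthetic$temperatures)))
  manifest <- generate_sweep_dataset(config$synthetic,
                                     file.path(out_dir, "rf"))
  message("[thermotex] reconstructing and extracting features")
  images_dir <- file.path(out_dir, "images")
  features <- extract_manifest_features(manifest, config, images_dir)
  features_csv <- file.path(out_dir, "features.csv")
  write_feature_table(features, features_csv)
  message("[thermotex] correlating features with temperature")
  series <- build_sample_series(features)
  summary <- aggregate_across_samples(series)
  summary_csv <- file.path(out_dir, "summary.csv")
  utils::write.csv(
    cbind(summary, config_hash = hash, seed = config$synthetic$seed),
    summary_csv, row.names = FALSE)
  top <- rank_features(summary, top_k)
  message(sprintf("[thermotex] done; top feature: %s (r = %.3f)",
                  top$feature[1], top$r_mean[1]))
  list(manifest = manifest, images_dir = images_dir,
       features_csv = features_csv, summary_csv = summary_csv,
       top_features = top, config_hash = hash)
}
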