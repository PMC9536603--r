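#!/usr/bin/env Rscript
# Stage 3: extract the 31 texture features per frame.
#
# Five 16 x 16 ROIs per image, placed away from the near field (32-row
# top margin) and the lateral edges (8 columns); each sample keeps the
# same ROI locations across its whole sweep. Per frame the feature
# vector is the mean over its ROIs: 3 histogram features, 4 GLCM
# features x 4 directions (L = 16, d = 1, symmetric), 12 GGCM
# statistics (Sobel gradient, 16 x 16 levels).
#
# Output: scratch/results/features.csv (738 rows x 33 columns).

library(thermotex)

manifest <- load_manifest("scratch/data/rf/manifest.csv")
cfg <- pipeline_config(rois_per_image = 5L, roi_seed = 1L)
features <- extract_manifest_features(manifest, cfg)

dir.create("scratch/results", recursive = TRUE, showWarnings = FALSE)
write_feature_table(features, "scratch/results/features.csv")

message(sprintf("feature table: %d rows x %d cols -> scratch/results/features.csv",
                nrow(features), ncol(features)))
message(sprintf("mean gray scale spans %.1f-%.1f across the dataset",
                min(features$glh.mean_gray_scale),
                max(features$glh.mean_gray_scale)))
message("next: 04_correlate.R")
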