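#!/usr/bin/env Rscript
# Stage 2: reconstruct B-mode images from the simulated RF frames.
#
# Per frame: blockwise-max envelope of the first 2048 samples per line
# (blocks of 4 -> 512 x 128 image), log compression, fixed full-scale
# dynamic-range mapping to 8 bits, 3x3 median filter. The fixed mapping
# (rather than each frame's own maximum) keeps gray levels comparable
# across temperatures, which is the point of the sweep.
#
# Output: scratch/data/images/*.tif (8-bit grayscale).

library(thermotex)

manifest <- load_manifest("scratch/data/rf/manifest.csv")
rc <- recon_config(normalization = "full_scale")
dir.create("scratch/data/images", recursive = TRUE, showWarnings = FALSE)

mgs <- numeric(0)
for (i in seq_len(nrow(manifest$entries))) {
  frame <- read_rf_frame(manifest$entries$frame_path[i])
  img <- reconstruct_bmode(frame, rc)
  write_bmode_tiff(img, sprintf("scratch/data/images/%s_T%05.1f.tif",
                                frame$sample_id, frame$temperature_c))
  if (frame$sample_id == "s01") mgs[as.character(frame$temperature_c)] <-
      mean(img$pixels)
}

message(sprintf("reconstructed %d images (512 x 128, 8-bit)",
                nrow(manifest$entries)))
message(sprintf("sample s01 whole-image mean gray: %.1f at 20 degC -> %.1f at 60 degC",
                mgs[["20"]], mgs[["60"]]))
message("images under scratch/data/images; next: 03_features.R")
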