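#!/usr/bin/env Rscript
# Stage 1: simulate the water-bath heating sweep.
#
# 18 synthetic tissue samples, each imaged at every degree from 20 to
# 60 degC with a 128-line 3.5 MHz probe sampled at 14 MHz. Each sample
# owns a frozen scatterer field and noise realization; across the sweep
# its frames differ only through the echogenicity gain (2%/degC below
# the 54 degC coagulation point, 0.2%/degC above). Frames are written in
# the package's versioned binary RF format plus a CSV manifest.
#
# Output: scratch/data/rf/ (~740 MB of RF frames; regenerable at will).

library(thermotex)

cfg <- synthetic_config(seed = 1L)
manifest <- generate_sweep_dataset(cfg, "scratch/data/rf")

print(manifest)
stopifnot(nrow(manifest$entries) ==
            cfg$n_samples * length(cfg$temperatures))
message(sprintf("gain spans %.0f -> %.0f ADC units over %g-%g degC",
                amplitude_at(min(cfg$temperatures), cfg),
                amplitude_at(max(cfg$temperatures), cfg),
                min(cfg$temperatures), max(cfg$temperatures)))
message("frames on disk under scratch/data/rf; next: 02_reconstruct.R")
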