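# thermotex

Texture-based ultrasonic thermometry: track tissue temperature during
hyperthermia from the texture of B-mode ultrasound images.

During therapeutic heating (mild hyperthermia at 42–45 °C, thermal
ablation above 60 °C), classical acoustic thermometry signals degrade
once tissue coagulates. The texture of the B-mode image keeps changing,
though: echogenicity rises with temperature and speckle statistics
shift, with a characteristic plateau after coagulation (~54 °C for
liver in vitro). `thermotex` implements the full analysis:

1. **B-mode reconstruction** from raw RF frames (128 lines × 4096
   int16 samples at 14 MHz): blockwise-max envelope over the first
   2048 samples per line (blocks of 4 → 512 × 128), log compression
   `log10(v + ε) − log10(ε)`, threshold + 8-bit mapping
   `min(⌊256·b/b_ref⌋, 255)`, 3 × 3 median filter.
2. **31 texture features** per 16 × 16 ROI: mean gray scale, SD and
   entropy of the gray-level histogram (GLH); contrast, correlation,
   energy and homogeneity of the gray-level co-occurrence matrix
   (GLCM; L = 16, d = 1) at 0°, 45°, 90°, 135°; and 12 statistics of
   the gray level–gradient co-occurrence matrix (GGCM; Sobel gradient,
   16 × 16 levels), e.g. hybrid entropy −Σ p log₂ p and inverse
   difference moment Σ p/(1+(i−j)²).
3. **Correlation analysis**: per-sample Pearson r (exact t-test p) of
   each feature against temperature, aggregated over samples as
   mean ± SD, mean-curve slopes split at the coagulation point, and
   ranking by |mean r|.
4. **A synthetic RF generator** (convolutional point-scatterer speckle,
   frozen tissue per sample, piecewise-linear echogenicity gain with a
   coagulation plateau) so the whole pipeline runs and is tested
   without real recordings.

## Worked example

```r
library(thermotex)

# one synthetic sample, imaged at 20 and at 60 degC
cfg <- synthetic_config(seed = 1)
img20 <- reconstruct_bmode(simulate_rf_frame("s01", 20, cfg),
                           recon_config(normalization = "full_scale"))
img60 <- reconstruct_bmode(simulate_rf_frame("s01", 60, cfg),
                           recon_config(normalization = "full_scale"))
c(mean(img20$pixels), mean(img60$pixels))
#> [1] 150.6507 160.0779

# texture features of one ROI
roi <- select_rois(img20, n_rois = 1, seed = 7)[[1]]
round(extract_features(roi)[c("glh.mean_gray_scale", "glh.entropy",
                              "glcm.homogeneity.45",
                              "ggcm.hybrid_entropy")], 3)
#> glh.mean_gray_scale         glh.entropy glcm.homogeneity.45
#>             150.809               5.481               0.584
#> ggcm.hybrid_entropy
#>               5.645
```

The mean gray level rises ~9.4 gray levels over the sweep because the
generator's echogenicity gain (2 %/°C, flattening to 0.2 %/°C above
54 °C) survives the fixed full-scale dynamic-range mapping; each ROI
yields the 31-feature vector used by the correlation stage.

The full study is the four scripts under `analysis/` (simulate →
reconstruct → extract → correlate), run from the repository root:

```sh
Rscript analysis/01_simulate.R     # 738 RF frames -> scratch/data/rf
Rscript analysis/02_reconstruct.R  # B-mode TIFFs  -> scratch/data/images
Rscript analysis/03_features.R     # feature table -> scratch/results
Rscript analysis/04_correlate.R    # summary + top-5 -> results/
```

The last stage prints, for the default seed:

```
top 5 features by |mean r| across 18 samples:
  1. ggcm.inertia                 r = +0.9933 +/- 0.0030  (mean p = 1.5e-32)
  2. glh.mean_gray_scale          r = +0.9923 +/- 0.0004  (mean p = 7.2e-37)
  3. glh.std                      r = +0.9897 +/- 0.0009  (mean p = 4.1e-34)
  4. glcm.contrast.0              r = +0.9868 +/- 0.0060  (mean p = 1.4e-27)
  5. glcm.contrast.45             r = +0.9866 +/- 0.0095  (mean p = 1.4e-23)
mean gray scale: slope 0.270 gray/degC below 54 degC, 0.037 above (plateau, ratio 7.3x)
```

i.e. the pipeline recovers the designed echogenicity trend (strong
positive mean-gray-scale correlation) and detects its coagulation
plateau. See `vignettes/texture-thermometry.Rmd` for what the
synthetic data does and does not emulate — second-order feature signs
on synthetic speckle are emergent, not calibrated to real tissue.

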