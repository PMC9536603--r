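---
title: "Tracking tissue temperature with B-mode texture: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking tissue temperature with B-mode texture: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Hyperthermia treatments — mild heating of a tumour to 42–45 °C, or
thermal ablation above 60 °C — need a noninvasive way to monitor tissue
temperature. Ultrasound is attractive for this (cheap, real-time, good
penetration), but the classical acoustic thermometry signals (echo
shifts, backscattered energy) lose sensitivity once tissue coagulates.
An alternative is to track the *texture* of the B-mode image itself:
as tissue heats, its echogenicity and speckle statistics change, and
first- and second-order gray-level statistics of image patches
correlate with temperature.

`thermotex` implements that analysis end to end for a water-bath style
experiment: raw radiofrequency (RF) frames per (sample, temperature)
→ B-mode reconstruction → 31 texture features per region of interest
(ROI) → per-sample Pearson correlation with temperature → aggregation
across samples and feature ranking. Because real heated-liver RF
recordings are not distributable with the package, a synthetic RF
generator reproduces the statistical structure the analysis relies on,
so the entire pipeline is exercised and tested without real data.

## B-mode reconstruction

Each RF frame holds 128 scan lines of 4096 signed 16-bit samples taken
at 14 MHz from a 3.5 MHz probe. Reconstruction (`reconstruct_bmode()`)
is deliberately minimal, avoiding transform-based envelope detectors:

1. **Envelope by blockwise maxima.** Only the first 2048 samples per
   line are used (the experimental depth is about half the sampled
   depth). The line is rectified and the maximum over each
   non-overlapping block of 4 samples taken, giving a 512 × 128
   envelope image. Rectification before the maximum matters: RF is
   zero-mean, and the maximum of raw signed samples would ignore
   negative half-cycles.
2. **Log compression.** `v -> log10(v + eps) - log10(eps)` with
   `eps = 1` by default, so a zero envelope maps to exactly 0 and the
   mapping is strictly increasing. The offset is configurable
   (`log_eps`); as `eps -> 0` the map tends to a pure `log10`, making
   the subsequent normalized mapping invariant to a global gain up to
   floor discretisation.
3. **Threshold and 8-bit mapping.** Values below a configurable
   threshold are suppressed to 0 (a compatibility flag maps them to the
   literal value 1 instead, for hardware that floors dark pixels);
   remaining values map through
   `pixel = min(floor(256 * b / b_ref), 255)`.
4. **Median filter.** A 3 × 3 median with edge replication removes
   isolated speckle outliers; kernel 1 disables it. The filter is a
   vectorised sorting network, so whole frames filter in milliseconds.

### The normalization reference

The choice of `b_ref` is the one place where single-image display and
sweep analysis genuinely conflict:

* `normalization = "frame_max"` (default) uses the frame's own maximum.
  Every nonzero frame then attains 255 somewhere — the right behaviour
  for displaying one image, and the contract all shape/range tests
  assume.
* `normalization = "full_scale"` uses the log-compressed full int16 ADC
  range, a constant. The sweep pipeline defaults to this, because a
  per-frame maximum normalizes *away* most of a multiplicative
  echogenicity change between frames — exactly the signal a temperature
  sweep is trying to measure. With a fixed reference, gray levels are
  comparable across temperatures and the mean gray scale tracks the
  gain.

The threshold default is 0 (no suppression): with the synthetic data's
homogeneous speckle there is no "outside the tissue" region to remove,
and suppression introduces a hard discontinuity at the threshold that
adds variance to gray statistics near it.

## The 31 texture features

Features are computed on 16 × 16-pixel ROIs (`select_rois()`), placed
uniformly at random inside the image minus a margin (32 rows at the
top for the near field, 8 columns at the sides), with a seed. Explicit
origins can be supplied instead (`extract_roi()`) to mimic manual
selection.

* **3 first-order (GLH) features** on the raw 8-bit patch: mean gray
  scale, standard deviation (the square root of the population
  variance; the variance itself is available from `glh_features()`),
  and Shannon entropy of the 256-level histogram in bits. Entropy is
  implemented as `-sum p log2 p` so that it is nonnegative and grows
  with disorder.
* **16 GLCM features**: the patch is quantized to L = 16 levels by
  uniform binning `floor(g * 16/256)`; co-occurrence matrices are built
  at distance d = 1 along 0°, 45°, 90° and 135°, counting each ordered
  pair and its reverse (symmetric convention, configurable) and
  normalizing by the pair count — the only normalization under which
  the entries sum to 1. From each matrix: contrast, correlation
  (defined as 0 when a marginal is degenerate, keeping downstream
  statistics total), energy, homogeneity.
* **12 GGCM statistics**: the joint histogram of quantized gray level
  (16 levels) and quantized Sobel gradient magnitude (16 levels; the
  patch maximum maps to the top level, rounded half-up; a
  central-difference operator is selectable). From it: small/large
  gradient preponderance, gray-level and gradient nonuniformity,
  energy, mean gradient, gradient mean square deviation, correlation,
  gradient entropy, hybrid entropy, inertia, and inverse difference
  moment, with 0-based level indices and `0 log 0 := 0`.

Every matrix constructor and every statistic is verified in the test
suite against independent brute-force loop oracles to 1e-10 on hundreds
of random patches, plus closed-form degenerate cases (constant patch,
two-level patch, uniform matrix).

## Correlation analysis

For one sample, each feature column (per-temperature value, averaged
over that image's ROIs) is correlated with the temperature grid by the
Pearson product-moment coefficient, with the exact two-sided t-test
p-value (n − 2 degrees of freedom; the 41-point grid makes this
standard). Degenerate columns yield r = 0, p = 1 with a flag rather
than an error. Across samples, `aggregate_across_samples()` reports the
mean and *sample* standard deviation (n − 1 denominator) of the
per-sample r values, the mean p-value, a Bonferroni-adjusted copy
(emitted for transparency, not used for ranking), and the slope of the
across-sample mean curve from a least-squares fit. `rank_features()`
orders by |mean r| with deterministic tie-breaks (smaller SD, then
name); `segment_slopes()` fits the mean curve separately below and
above a breakpoint (default 54 °C) to quantify the coagulation plateau.

## The synthetic generator

`synthetic_config()` encodes the study conditions: 18 samples, 20–60 °C
in 1 °C steps, 128 × 4096 int16 frames. The speckle model is the
standard convolutional one: per scan line, a sparse train of point
scatterers (Poisson count at 0.1 per sample interval, uniform
positions, Gaussian reflectivities) convolved with a Gaussian-windowed
3-cycle 3.5 MHz sinusoid sampled at 14 MHz, plus additive Gaussian
noise (SD 5 % of the base amplitude), rounded to int16 with an explicit
clipping check.

Temperature enters *only* as a multiplicative echogenicity gain:
`a0 * (1 + 0.02 (T - 20))` up to 54 °C, then continuing at 0.002 per °C
— rising echo intensity with a coagulation plateau. The slopes are
package choices (no quantitative echogenicity-vs-temperature curve is
established for this setting); 2 %/°C gives a clearly measurable trend
without int16 clipping at 60 °C for the default `a0 = 2000`, and the
10× smaller plateau slope makes the two regimes separable by a
two-segment fit. Both are exposed in the config.

Two deliberate freezes make the sweep a controlled experiment:

* **The scatterer field is frozen per sample** — the water bath heats
  the *same* tissue, so inter-temperature texture change must come from
  the gain model, not from resampled speckle.
* **The noise realization is frozen per sample too.** All streams are
  derived by hashing (master seed, sample id, role), so adding samples
  never shifts existing ones, and the frames of one sample differ
  across temperature only through the gain. With noise redrawn per
  acquisition instead, the plateau's 0.2 %/°C gain (≈ 0.04 gray
  levels/°C in the across-sample ROI mean) would be smaller than the
  redraw jitter of that mean (≈ 0.1 gray levels SD), and the monotone
  design of the generator would be unobservable at the pipeline's
  output at this noise level.

### What the generator does and does not emulate

It reproduces: speckle with a right-skewed (Rayleigh-like) envelope
histogram; a monotone echogenicity trend with a plateau; frozen tissue
across the sweep; realistic frame geometry and bit depth. It does
*not* emulate frequency-dependent attenuation, beamforming, tissue
inhomogeneity, or the structural homogenization of coagulating tissue.
Consequently, passing the recovery tests shows the *pipeline* recovers
an encoded echogenicity trend; it does not certify the real-tissue
behaviour of second-order features. In particular, on synthetic sweeps
the gain raises speckle contrast, so GLCM contrast correlates
*positively* and homogeneity *negatively* with temperature — real
coagulating liver shows the opposite signs, driven by structural
change the generator does not model. Only the mean-gray-scale recovery
(strong positive correlation, plateau) is a designed property.

## Numerical choices and problem sizes

* Seeds: one master seed; child streams via a string hash into
  `[0, 2^31)`. RNG state is saved and restored around every seeded
  operation.
* Temperatures are compared on a 1e-6 °C grid for manifest
  deduplication; ragged temperature grids warn rather than fail.
* Feature CSVs are written with 17 significant digits, so a
  write/read cycle is lossless for doubles; RF files round-trip
  bit-exactly.
* The analysis scripts and acceptance checks run the full study size —
  18 samples × 41 temperatures = 738 frames, 5 ROIs per image — which
  completes in a few minutes on one core; unit tests use reduced
  geometries (fewer lines/samples) that exercise identical code paths.

## Limitations

The generator's echogenicity slopes are stipulations, not measurements;
absolute r values on synthetic data (≈ 0.99 for mean gray scale) are
optimistic relative to real tissue, where biological variability
between samples widens the spread. The reconstruction omits time-gain
compensation and scan conversion on purpose (the analysis operates on
the raw geometry). ROI placement assumes the whole image is tissue;
there is no segmentation.
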