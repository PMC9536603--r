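# Synthetic RF data generator.
#
# A convolutional point-scatterer speckle model: each tissue sample owns a
# frozen random scatterer field (positions and reflectivities per scan
# line); the RF trace of a line is that impulse train convolved with a
# Gaussian-windowed sinusoidal pulse at the transducer centre frequency,
# plus additive electronic noise. Temperature enters only as a
# multiplicative echogenicity gain that rises linearly up to the
# coagulation temperature and much more slowly above it.

#' Configuration of the synthetic heating-sweep dataset
#'
#' Defaults emulate a water-bath heating experiment: 18 tissue samples
#' imaged at every degree from 20 to 60 degC with a 128-line, 3.5 MHz
#' probe sampled at 14 MHz, echogenicity rising 2% per degC until tissue
#' coagulates at 54 degC and 0.2% per degC beyond.
#'
#' @param n_samples number of tissue samples (default 18).
#' @param temperatures strictly increasing degC grid (default 20:60).
#' @param n_lines scan lines per frame (default 128).
#' @param n_samples_per_line RF samples per line (default 4096).
#' @param center_freq_hz pulse centre frequency (default 3.5 MHz).
#' @param sample_rate_hz sampling rate (default 14 MHz).
#' @param pulse_cycles carrier cycles in the Gaussian-windowed pulse
#'   (default 3).
#' @param scatterer_density mean scatterers per RF sample interval
#'   (default 0.1).
#' @param base_amplitude echo amplitude scale a0 at 20 degC, in raw ADC
#'   units (default 2000; small enough that int16 never clips at 60 degC).
#' @param trend_slope fractional echogenicity gain per degC below
#'   `coag_temp_c` (default 0.02).
#' @param coag_temp_c coagulation temperature (default 54).
#' @param plateau_slope fractional gain per degC above `coag_temp_c`
#'   (default 0.002); must be smaller than `trend_slope`.
#' @param noise_sigma additive Gaussian noise SD as a fraction of
#'   `base_amplitude` (default 0.05).
#' @param seed master seed; every stream is derived from it.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_samples = 18L,
                             temperatures = 20:60,
                             n_lines = 128L,
                             n_samples_per_line = 4096L,
                             center_freq_hz = 3.5e6,
                             sample_rate_hz = 14e6,
                             pulse_cycles = 3L,
                             scatterer_density = 0.1,
                             base_amplitude = 2000,
                             trend_slope = 0.02,
                             coag_temp_c = 54,
                             plateau_slope = 0.002,
                             noise_sigma = 0.05,
                             seed = 1L) {
  temperatures <- as.numeric(temperatures)
  if (any(diff(temperatures) <= 0))
    stop("temperatures must be strictly increasing")
  if (coag_temp_c < 20 || coag_temp_c > 60)
    stop("coag_temp_c must lie in [20, 60]")
  if (!(trend_slope > plateau_slope && plateau_slope >= 0))
    stop("need trend_slope > plateau_slope >= 0")
  structure(list(n_samples = as.integer(n_samples),
                 temperatures = temperatures,
                 n_lines = as.integer(n_lines),
                 n_samples_per_line = as.integer(n_samples_per_line),
                 center_freq_hz = center_freq_hz,
                 sample_rate_hz = sample_rate_hz,
                 pulse_cycles = as.integer(pulse_cycles),
                 scatterer_density = scatterer_density,
                 base_amplitude = base_amplitude,
                 trend_slope = trend_slope,
                 coag_temp_c = coag_temp_c,
                 plateau_slope = plateau_slope,
                 noise_sigma = noise_sigma,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Echogenicity gain at a given temperature
#'
#' Piecewise-linear gain: `a0 * (1 + k * (T - 20))` up to the coagulation
#' temperature, then continuing from that value with the (much smaller)
#' plateau slope. Strictly increasing in temperature.
#'
#' @param temperature_c temperature in degC, within the configured range.
#' @param config a [synthetic_config()].
#' @return Scalar gain in raw ADC units.
#' @export
amplitude_at <- function(temperature_c, config) {
  rng <- range(config$temperatures)
  if (temperature_c < rng[1] || temperature_c > rng[2])
    stop(sprintf("temperature %.3f outside configured range [%g, %g]",
                 temperature_c, rng[1], rng[2]))
  a0 <- config$base_amplitude
  tc <- config$coag_temp_c
  if (temperature_c <= tc) {
    a0 * (1 + config$trend_slope * (temperature_c - 20))
  } else {
    g_coag <- a0 * (1 + config$trend_slope * (tc - 20))
    g_coag * (1 + config$plateau_slope * (temperature_c - tc))
  }
}

#' Frozen scatterer field of one tissue sample
#'
#' Per scan line, scatterer sample positions (0-based indices, without
#' replacement) and Gaussian reflectivities. Depends only on the master
#' seed and the sample id, so the same tissue is "imaged" at every
#' temperature; only the echogenicity gain changes across the sweep.
#'
#' @param sample_id sample identifier.
#' @param config a [synthetic_config()].
#' @return List with integer vectors `line` (1-based), `pos` (0-based
#'   sample index) and numeric `amp`.
#' @export
scatterer_field <- function(sample_id, config) {
  n <- config$n_samples_per_line
  with_seed(derive_seed(config$seed, sample_id, "scatterers"), {
    counts <- stats::rpois(config$n_lines, config$scatterer_density * n)
    counts <- pmin(counts, n)
    pos <- unlist(lapply(counts, function(k) sample.int(n, k) - 1L),
                  use.names = FALSE)
    list(line = rep.int(seq_len(config$n_lines), counts),
         pos = as.integer(pos),
         amp = stats::rnorm(sum(counts)))
  })
}

# Gaussian-windowed sinusoid at the centre frequency; odd length so a
# scatterer stays centred on its sample position.
pulse_kernel <- function(config) {
  fs <- config$sample_rate_hz
  f0 <- config$center_freq_hz
  half <- ceiling(config$pulse_cycles / f0 * fs / 2)
  t <- (-half:half) / fs
  sigma <- (config$pulse_cycles / f0) / 6
  sin(2 * pi * f0 * t) * exp(-t^2 / (2 * sigma^2))
}

#' Simulate one RF frame
#'
#' Convolves the sample's frozen scatterer train, scaled by
#' [amplitude_at()], with the pulse kernel, adds Gaussian noise, and
#' rounds to int16. Deterministic given (seed, sample_id, temperature).
#'
#' @param sample_id sample identifier.
#' @param temperature_c temperature in degC.
#' @param config a [synthetic_config()].
#' @return An [rf_frame()].
#' @export
simulate_rf_frame <- function(sample_id, temperature_c, config) {
  n <- config$n_samples_per_line
  n_lines <- config$n_lines
  field <- scatterer_field(sample_id, config)
  gain <- amplitude_at(temperature_c, config)

  p <- pulse_kernel(config)
  half <- (length(p) - 1L) %/% 2L
  # lay the pulse down at each scatterer by one scatter-add per tap on a
  # per-line padded index space; within a tap the target indices are
  # unique (positions are unique per line), so `v[idx] + x` is safe
  n_pad <- n + 2L * half
  v <- numeric(n_pad * n_lines)
  if (length(field$pos)) {
    g <- (field$line - 1L) * n_pad + field$pos + half + 1L
    for (k in seq_along(p)) {
      idx <- g + (k - 1L - half)
      v[idx] <- v[idx] + p[k] * field$amp
    }
  }
  rf <- matrix(v, n_pad, n_lines)[half + seq_len(n), , drop = FALSE]
  rf <- gain * rf
  if (config$noise_sigma > 0) {
    # like the scatterer field, the noise realization is frozen per
    # sample: across the sweep the frames of one sample differ only
    # through the echogenicity gain
    noise_seed <- derive_seed(config$seed, sample_id, "noise")
    rf <- rf + with_seed(noise_seed,
      matrix(stats::rnorm(n * n_lines,
                          sd = config$noise_sigma * config$base_amplitude),
             n, n_lines))
  }
  rf <- round(rf)
  if (max(abs(rf)) > 32767)
    stop("synthetic RF clips the int16 range; reduce base_amplitude")
  rf_frame(t(rf), sample_rate_hz = config$sample_rate_hz,
           center_freq_hz = config$center_freq_hz,
           sample_id = sample_id, temperature_c = temperature_c)
}

#' Sample identifiers of a configured sweep
#'
#' @param config a [synthetic_config()].
#' @return Character vector `s01`, `s02`, ...
#' @export
sweep_sample_ids <- function(config) {
  sprintf("s%02d", seq_len(config$n_samples))
}

#' Generate a full heating-sweep dataset on disk
#'
#' Writes one RF frame file per (sample, temperature) plus a
#' `manifest.csv`, then loads and returns the manifest.
#'
#' @param config a [synthetic_config()].
#' @param out_dir output directory (created if needed).
#' @return A `dataset_manifest`.
#' @export
generate_sweep_dataset <- function(config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ids <- sweep_sample_ids(config)
  entries <- expand.grid(temperature_c = config$temperatures,
                         sample_id = ids, stringsAsFactors = FALSE)
  entries <- entries[c("sample_id", "temperature_c")]
  entries$frame_path <- sprintf("%s_T%05.1f.usrf", entries$sample_id,
                                entries$temperature_c)
  for (i in seq_len(nrow(entries))) {
    frame <- simulate_rf_frame(entries$sample_id[i],
                               entries$temperature_c[i], config)
    write_rf_frame(frame, file.path(out_dir, entries$frame_path[i]))
  }
  manifest_path <- file.path(out_dir, "manifest.csv")
  write_manifest(entries, manifest_path)
  load_manifest(manifest_path)
}
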