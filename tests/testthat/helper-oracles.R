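# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: the Fisher oracle enumerates the hypergeometric
# support with lchoose(), the band-RMS oracle filters in the time domain
# with a long windowed-sinc FIR, and the dispersion oracle searches windows
# exhaustively.

# Two-sided Fisher p by exhaustive enumeration over the support, summing
# probabilities of tables no more probable than the observed one.
oracle_fisher_p <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; N <- a + b + c + d
  k <- max(0, c1 - (N - r1)):min(r1, c1)
  lp <- lchoose(r1, k) + lchoose(N - r1, c1 - k) - lchoose(N, c1)
  p <- exp(lp)
  sum(p[p <= p[k == a] * (1 + 1e-7)])
}

# Time-domain band RMS via zero-phase windowed-sinc FIR band-pass.
oracle_band_rms <- function(x, fs, band = c(0.9, 15), ntaps = 2048) {
  h <- signal::fir1(ntaps, band / (fs / 2), type = "pass")
  xf <- signal::filtfilt(signal::Ma(h), x)
  sqrt(mean(xf^2))
}

# Exhaustive symmetric-window search for the 68% dispersion on the grid:
# checks every candidate half-width (distance from the median to a grid
# point) by direct mass summation.
oracle_dispersion <- function(spectrum) {
  f <- spectrum$band_freq
  m <- spectrum$band_power * spectrum$df
  med <- median_frequency(spectrum)
  tot <- sum(m)
  widths <- sort(unique(abs(f - med)))
  cover <- vapply(widths, function(w) sum(m[abs(f - med) <= w + 1e-12]) / tot,
                  numeric(1))
  2 * widths[which(cover >= 0.68)[1]]
}

# Mass fraction of a spectrum in [lo, hi] (closed/closed or open lower edge),
# by direct summation, for band-fraction and harmonic-index cross-checks.
oracle_mass_fraction <- function(spectrum, lo, hi, open_lower = FALSE) {
  f <- spectrum$band_freq
  m <- spectrum$band_power * spectrum$df
  sel <- if (open_lower) f > lo + 1e-9 & f <= hi + 1e-9
         else f >= lo - 1e-9 & f <= hi + 1e-9
  sum(m[sel]) / sum(m)
}

# Multi-component sinusoid test record.
sine_record <- function(freqs, amps = 1, fs = 128, dur = 16, phases = 0,
                        axes = 1, ...) {
  amps <- rep_len(amps, length(freqs))
  phases <- rep_len(phases, length(freqs))
  t <- seq_len(fs * dur) / fs
  x <- rowSums(mapply(function(f, a, p) a * sin(2 * pi * f * t + p),
                      freqs, amps, phases))
  accel_record(matrix(rep(x, axes), ncol = axes), fs, ...)
}

# Synthetic flat-density spectrum over the analysis band (unit density).
flat_band_spectrum <- function(config = spectral_config(), df = 0.25) {
  freq <- seq(0, 64, by = df)
  inb <- freq >= config$band[1] - 1e-9 & freq <= config$band[2] + 1e-9
  power <- as.numeric(inb)
  structure(list(freq = freq, power = power, df = df,
                 band_freq = freq[inb], band_power = power[inb],
                 variance = sum(power) * df, config = config,
                 subject_id = "flat", condition = "rest", side = "R"),
            class = "tremor_spectrum")
}

# Small labelled cohort with attached metrics, built from explicit values.
metrics_cohort <- function(values) {
  # values: data.frame with subject_id, group and <cond>_<side>_<metric> cols
  values
}

# Feature vectors at the three archetype population means (side-averaged,
# ratio of cell means per side then averaged), computed from the published
# group tables carried by the archetypes.
archetype_mean_features <- function(group) {
  cells <- tremor_archetype(group)$cells
  g <- function(cond, side, what)
    cells[[what]][cells$condition == cond & cells$side == side]
  list(rest_cf = mean(c(g("rest", "R", "cf_mean"), g("rest", "L", "cf_mean"))),
       postural_cf = mean(c(g("postural", "R", "cf_mean"),
                            g("postural", "L", "cf_mean"))),
       intensity_ratio = mean(c(
         g("postural", "R", "intensity_mean") / g("rest", "R", "intensity_mean"),
         g("postural", "L", "intensity_mean") / g("rest", "L", "intensity_mean"))))
}
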