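#' Recording specification for the simulator
#'
#' Sampling settings for rendered signals. Defaults (128 Hz, 16 s) give at
#' least 8-fold oversampling of the 15 Hz band top and a 0.25 Hz spectral
#' grid with 4 s Welch segments.
#'
#' @param sampling_rate Hz, at least 64.
#' @param duration seconds, at least 8.
#' @param seed optional integer seed; with a fixed seed rendered output is
#'   bit-identical across runs.
#' @return A `signal_spec` list.
#' @export
signal_spec <- function(sampling_rate = 128, duration = 16, seed = NULL) {
  sampling_rate <- check_scalar(sampling_rate, "sampling_rate")
  duration <- check_scalar(duration, "duration")
  if (sampling_rate < 64)
    stop_tremor("'sampling_rate' must be >= 64 Hz (band of interest reaches 15 Hz)")
  if (duration < 8) stop_tremor("'duration' must be >= 8 s")
  if (!is.null(seed)) seed <- as.integer(check_scalar(seed, "seed"))
  structure(list(sampling_rate = sampling_rate, duration = duration,
                 seed = seed), class = "signal_spec")
}

#' Signal-level tremor component parameters
#'
#' The forward model behind one rendered recording: a harmonic core of
#' amplitude `amplitude` (m/s^2) whose instantaneous frequency wanders around
#' `center_freq` (Hz) as a mean-reverting (Ornstein-Uhlenbeck) process with
#' stationary standard deviation `freq_jitter_sd` (Hz) and correlation
#' timescale `jitter_timescale` (s), plus broadband Gaussian noise of RMS
#' `noise_floor_rms` (m/s^2) band-limited to the analysis band. The harmonic
#' fraction (share of total band power carried by the core,
#' `amplitude^2/2 / (amplitude^2/2 + noise_floor_rms^2)`) is stored as a
#' derived field; the implied total band RMS is
#' `sqrt(amplitude^2/2 + noise_floor_rms^2)`.
#'
#' @param amplitude harmonic core amplitude, m/s^2, `>= 0`.
#' @param center_freq core frequency in Hz, strictly inside (0.9, 15).
#' @param freq_jitter_sd instantaneous-frequency wander SD, Hz.
#' @param jitter_timescale wander correlation timescale, s.
#' @param noise_floor_rms band-limited noise RMS, m/s^2.
#' @return A `tremor_component` list with derived fields `harmonic_fraction`
#'   and `implied_intensity`.
#' @export
tremor_component <- function(amplitude, center_freq, freq_jitter_sd = 0,
                             jitter_timescale = 1, noise_floor_rms = 0) {
  amplitude <- check_scalar(amplitude, "amplitude")
  center_freq <- check_scalar(center_freq, "center_freq")
  freq_jitter_sd <- check_scalar(freq_jitter_sd, "freq_jitter_sd")
  jitter_timescale <- check_scalar(jitter_timescale, "jitter_timescale")
  noise_floor_rms <- check_scalar(noise_floor_rms, "noise_floor_rms")
  if (amplitude < 0) stop_tremor("'amplitude' must be >= 0")
  if (center_freq <= 0.9 || center_freq >= 15)
    stop_tremor("'center_freq' must lie strictly inside (0.9, 15) Hz")
  if (freq_jitter_sd < 0 || noise_floor_rms < 0 || jitter_timescale <= 0)
    stop_tremor("jitter/noise parameters must be non-negative (timescale > 0)")
  core_p <- amplitude^2 / 2
  tot_p <- core_p + noise_floor_rms^2
  structure(list(
    amplitude = amplitude, center_freq = center_freq,
    freq_jitter_sd = freq_jitter_sd, jitter_timescale = jitter_timescale,
    noise_floor_rms = noise_floor_rms,
    harmonic_fraction = if (tot_p > 0) core_p / tot_p else 1,
    implied_intensity = sqrt(tot_p)), class = "tremor_component")
}

#' Tremor component from spectral-summary targets
#'
#' Builds a [tremor_component] whose rendered signal has total band RMS
#' `intensity`, whose harmonic core carries `harmonic_fraction` of band
#' power, and whose population center-frequency estimate is unbiased for
#' `center_freq`: because the flat band noise contributes a mean frequency
#' of `(0.9 + 15)/2 = 7.95` Hz to the power-weighted average, the core is
#' placed at `(center_freq - (1 - h) * 7.95) / h` (clamped to `[1, 14.5]` Hz).
#'
#' @param intensity target band RMS, m/s^2.
#' @param center_freq target power-weighted mean frequency, Hz.
#' @param harmonic_fraction share of band power in the harmonic core, `[0, 1]`.
#' @param freq_jitter_sd,jitter_timescale as in [tremor_component].
#' @return A [tremor_component].
#' @export
component_from_targets <- function(intensity, center_freq,
                                   harmonic_fraction = 0.95,
                                   freq_jitter_sd = 0.25,
                                   jitter_timescale = 1) {
  intensity <- check_scalar(intensity, "intensity")
  h <- check_scalar(harmonic_fraction, "harmonic_fraction")
  if (intensity < 0) stop_tremor("'intensity' must be >= 0")
  if (h < 0 || h > 1) stop_tremor("'harmonic_fraction' must lie in [0, 1]")
  noise_mean_f <- (0.9 + 15) / 2
  f0 <- if (h > 0) (center_freq - (1 - h) * noise_mean_f) / h else center_freq
  f0 <- min(max(f0, 1.0), 14.5)
  tremor_component(amplitude = sqrt(2 * h) * intensity, center_freq = f0,
                   freq_jitter_sd = freq_jitter_sd,
                   jitter_timescale = jitter_timescale,
                   noise_floor_rms = sqrt(1 - h) * intensity)
}

# Gaussian noise band-limited to [lo, hi] Hz by FFT masking, scaled to
# exact RMS `rms`.
render_band_noise <- function(n, fs, rms, lo = 0.9, hi = 15) {
  if (rms <= 0) return(numeric(n))
  z <- rnorm(n)
  f <- c(seq(0, floor(n / 2)), seq(-(ceiling(n / 2) - 1), -1)) * fs / n
  Z <- fft(z)
  Z[!(abs(f) >= lo & abs(f) <= hi)] <- 0 + 0i
  x <- Re(fft(Z, inverse = TRUE)) / n
  x / sqrt(mean(x^2)) * rms
}

# Ornstein-Uhlenbeck frequency wander: AR(1) with stationary sd `sd` and
# correlation time `tau`, initialized from the stationary distribution.
render_ou <- function(n, dt, sd, tau) {
  if (sd <= 0) return(numeric(n))
  rho <- exp(-dt / tau)
  innov <- rnorm(n) * sd * sqrt(1 - rho^2)
  innov[1] <- rnorm(1) * sd
  as.numeric(stats::filter(innov, rho, method = "recursive"))
}

#' Render a synthetic tremor acceleration recording
#'
#' Forward model for the spectral tremor parameters: the rendered signal is
#' `a(t) = A * sin(2 * pi * phi(t)) + n(t)` with instantaneous frequency
#' `dphi/dt = center_freq + OU jitter` and `n(t)` Gaussian noise band-limited
#' to 0.9-15 Hz, each axis an independent realization of the same component
#' parameters. The harmonic core has RMS `A/sqrt(2)` and the noise RMS is
#' scaled exactly, so total band RMS equals the component's implied
#' intensity. Deterministic under a fixed `spec$seed`.
#'
#' @param params a [tremor_component].
#' @param spec a [signal_spec].
#' @param axes 1 or 2 accelerometer axes.
#' @param subject_id,condition,side labels attached to the record.
#' @return An [accel_record].
#' @examples
#' rec <- render_tremor_signal(tremor_component(1, 7), signal_spec(seed = 1))
#' sqrt(mean(rec$samples^2))  # ~ 1/sqrt(2)
#' @export
render_tremor_signal <- function(params, spec = signal_spec(), axes = 2,
                                 subject_id = "S1", condition = "rest",
                                 side = "R") {
  stopifnot(inherits(params, "tremor_component"), inherits(spec, "signal_spec"))
  axes <- as.integer(axes)
  if (!axes %in% 1:2) stop_tremor("'axes' must be 1 or 2")
  if (spec$sampling_rate < 2 * 15)
    stop_tremor("sampling rate below twice the 15 Hz band top")
  n <- round(spec$sampling_rate * spec$duration)
  dt <- 1 / spec$sampling_rate
  render_axis <- function() {
    core <- 0
    if (params$amplitude > 0) {
      jitter <- render_ou(n, dt, params$freq_jitter_sd, params$jitter_timescale)
      phase <- cumsum(params$center_freq + jitter) * dt
      core <- params$amplitude * sin(2 * pi * phase)
    }
    core + render_band_noise(n, spec$sampling_rate, params$noise_floor_rms)
  }
  samples <- with_seed(spec$seed, {
    vapply(seq_len(axes), function(a) render_axis(), numeric(n))
  })
  accel_record(samples, spec$sampling_rate, subject_id = subject_id,
               condition = condition, side = side)
}
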