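test_that("intensity of a sinusoid is A/sqrt(2) through the spectral path", {
  for (A in c(1, 2.277)) {
    sp <- tremor_spectrum(sine_record(7, A))
    expect_equal(tremor_intensity(sp), A / sqrt(2), tolerance = 5e-3)
  }
  # the welders' postural-R group mean intensity corresponds to A = 2.277
  expect_equal(tremor_intensity(tremor_spectrum(sine_record(7, 2.277))),
               1.61, tolerance = 5e-3)
})

test_that("intensity agrees with a time-domain band-pass RMS oracle on band noise", {
  for (s in 1:4) {
    rec <- render_tremor_signal(
      tremor_component(0.6, 5.5, freq_jitter_sd = 0.5, noise_floor_rms = 0.3),
      signal_spec(seed = s), axes = 1)
    sp <- tremor_spectrum(rec)
    expect_equal(tremor_intensity(sp)^2,
                 oracle_band_rms(rec$samples[, 1], 128)^2,
                 tolerance = 0.01)
  }
})

test_that("center frequency: single line, symmetric pair, and band bounds", {
  expect_equal(center_frequency(tremor_spectrum(sine_record(7))), 7,
               tolerance = 0.1 / 7)
  expect_equal(center_frequency(tremor_spectrum(sine_record(c(5, 9),
                                                phases = c(0, 1.1)))),
               7, tolerance = 0.1 / 7)
  for (s in 1:5) {
    sp <- tremor_spectrum(render_tremor_signal(
      tremor_component(runif(1, 0.2, 2), runif(1, 2, 12),
                       freq_jitter_sd = runif(1, 0, 1),
                       noise_floor_rms = runif(1, 0, 0.5)),
      signal_spec(seed = s)))
    expect_gte(center_frequency(sp), 0.9)
    expect_lte(center_frequency(sp), 15)
    expect_gte(median_frequency(sp), 0.9)
    expect_lte(median_frequency(sp), 15)
  }
})

test_that("dispersion: concentrated lines are narrow, twin lines span the gap", {
  expect_lte(frequency_dispersion(tremor_spectrum(sine_record(7))), 0.5)
  # oracle-derived expectation for the equal twin-line spectrum
  sp2 <- tremor_spectrum(sine_record(c(5, 9), phases = c(0, 0.7)))
  expect_equal(frequency_dispersion(sp2), oracle_dispersion(sp2))
  expect_equal(frequency_dispersion(sp2), 4, tolerance = 0.5 / 4)
})

test_that("dispersion window contains at least 68% of band power and is grid-minimal", {
  for (s in 1:8) {
    sp <- tremor_spectrum(render_tremor_signal(
      tremor_component(runif(1, 0.1, 2), runif(1, 2.5, 12),
                       freq_jitter_sd = runif(1, 0, 1.5),
                       noise_floor_rms = runif(1, 0, 0.6)),
      signal_spec(seed = 100 + s)))
    d <- frequency_dispersion(sp)
    med <- median_frequency(sp)
    m <- sp$band_power * sp$df
    inside <- abs(sp$band_freq - med) <= d / 2 + 1e-12
    expect_gte(sum(m[inside]) / sum(m), 0.68)
    expect_equal(d, oracle_dispersion(sp))
  }
})

test_that("band energy fractions localize single lines and split a flat spectrum by bandwidth", {
  expect_equal(unname(band_energy_fractions(
    tremor_spectrum(sine_record(5)))), c(1, 0), tolerance = 1e-3)
  expect_equal(unname(band_energy_fractions(
    tremor_spectrum(sine_record(8)))), c(0, 1), tolerance = 1e-3)
  fl <- flat_band_spectrum()
  fr <- band_energy_fractions(fl)
  expect_equal(unname(fr["low"]), oracle_mass_fraction(fl, 3, 6.5))
  expect_equal(unname(fr["high"]),
               oracle_mass_fraction(fl, 6.5, 10, open_lower = TRUE))
  expect_equal(unname(fr), c(0.248, 0.248), tolerance = 0.07)
  expect_lte(sum(fr), 1)
})

test_that("harmonic index: 1.00 for a single harmonic, ~0.5 for twin lines, small for flat", {
  expect_gte(harmonic_index(tremor_spectrum(sine_record(7))), 0.99)
  expect_equal(round(harmonic_index(tremor_spectrum(sine_record(7))), 2), 1)
  sp2 <- tremor_spectrum(sine_record(c(5, 9)))
  expect_equal(harmonic_index(sp2),
               oracle_mass_fraction(sp2, 5 - 0.5, 5 + 0.5), tolerance = 1e-9)
  expect_equal(harmonic_index(sp2), 0.5, tolerance = 0.02)
  fl <- flat_band_spectrum()
  expect_equal(harmonic_index(fl), oracle_mass_fraction(fl, 0.5, 1.5))
  expect_equal(harmonic_index(fl), 1 / 14.1, tolerance = 0.3)
  expect_gt(harmonic_index(fl), 0)
})

test_that("degenerate inputs raise undefined-metric errors", {
  zero <- accel_record(numeric(2048), 128)
  expect_error(tremor_metrics(zero), "undefined",
               class = "tremorspec_undefined_metric")
  dc <- accel_record(rep(3.2, 2048), 128)
  expect_error(center_frequency(tremor_spectrum(dc)), "undefined")
})

test_that("rescaling the signal scales intensity and leaves shape metrics fixed", {
  rec <- render_tremor_signal(
    tremor_component(0.7, 6.8, freq_jitter_sd = 0.4, noise_floor_rms = 0.2),
    signal_spec(seed = 21), axes = 1)
  m0 <- tremor_metrics(rec)
  for (c_ in c(2, 0.1)) {
    mc <- tremor_metrics(accel_record(rec$samples * c_, 128))
    expect_equal(mc$intensity, abs(c_) * m0$intensity, tolerance = 1e-6)
    for (col in c("center_freq", "median_freq", "dispersion",
                  "low_band_fraction", "high_band_fraction", "harmonic_index"))
      expect_equal(mc[[col]], m0[[col]], tolerance = 1e-6)
  }
})

test_that("metrics compose deterministically and report all fields", {
  rec <- render_tremor_signal(tremor_component(1, 7, noise_floor_rms = 0.1),
                              signal_spec(seed = 4))
  m1 <- tremor_metrics(rec); m2 <- tremor_metrics(rec)
  expect_identical(m1, m2)
  expect_true(all(c("intensity", "center_freq", "median_freq", "dispersion",
                    "low_band_fraction", "high_band_fraction",
                    "harmonic_index") %in% names(m1)))
  expect_gt(m1$harmonic_index, 0)
  expect_lte(m1$harmonic_index, 1)
})
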