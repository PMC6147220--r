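# Stimulus synthesis: noise generation, amplitude modulation, ramps,
# level handling, windowed power.

test_that("GWN generation is deterministic and seeds decorrelate noises", {
  a <- generate_gwn(7, 150)
  b <- generate_gwn(7, 150)
  expect_identical(a$samples, b$samples)
  expect_lt(abs(mean(a$samples)), 1e-10)

  seeds <- matrix(seq_len(200), ncol = 2)
  r <- apply(seeds, 1, function(s) {
    stats::cor(generate_gwn(s[1], 150)$samples,
               generate_gwn(s[2] + 1000, 150)$samples)
  })
  expect_true(all(abs(r) < 0.05))
})

test_that("GWN is band-limited with at least 40 dB out-of-band rejection", {
  w <- generate_gwn(3, 150)
  n <- length(w$samples)
  spec <- Mod(stats::fft(w$samples))^2
  f <- (seq_len(n) - 1) * w$fs_hz / n
  absf <- pmin(f, w$fs_hz - f)
  inband <- absf >= 500 & absf <= 20000
  p_in <- sum(spec[inband])
  p_out <- sum(spec[!inband])
  expect_gt(10 * log10(p_in / max(p_out, .Machine$double.xmin)), 40)
})

test_that("generation rejects passbands outside Nyquist", {
  expect_error(generate_gwn(1, 150, band_hz = c(500, 30000)), "passband")
  expect_error(generate_gwn(1, 150, band_hz = c(0, 20000)), "passband")
})

test_that("amplitude modulation preserves RMS and honors the envelope convention", {
  w <- generate_gwn(11, 400)
  expect_identical(apply_am(w, 120, 0, depth = 0)$samples, w$samples)
  for (ph in c(0, pi / 3, pi)) {
    m <- apply_am(w, 120, ph, depth = 1)
    expect_lt(abs(20 * log10(rms_of(m) / rms_of(w))), 0.1)
  }
  # phase 0 starts at the envelope minimum: first sample is silenced
  m0 <- apply_am(generate_gwn(2, 400), 5, 0, 1)
  expect_lt(abs(m0$samples[1]), 1e-9)
  expect_gt(abs(generate_gwn(2, 400)$samples[1]), 0)
  expect_error(apply_am(w, 120, 0, depth = 1.5), "depth")
})

test_that("ramps scale edges to zero and the mid-ramp sample by one half", {
  w <- waveform(rep(1, 1000), 1000)
  expect_identical(apply_ramp(w, 0)$samples, w$samples)
  r <- apply_ramp(w, 100)  # 100-sample ramps
  expect_equal(r$samples[1], 0)
  expect_equal(r$samples[1000], 0)
  expect_equal(r$samples[51], sin(pi / 4)^2)   # (i-1)/nr = 0.5
  expect_equal(r$samples[950], cos(pi / 4)^2)  # j/nr = 0.5 from the end
  expect_true(all(r$samples[101:900] == 1))
  expect_error(apply_ramp(w, 600), "half")
})

test_that("set_level places RMS exactly and is invertible", {
  w <- generate_gwn(5, 150)
  expect_equal(rms_of(set_level(w, 0, reference_rms = 1)), 1, tolerance = 1e-12)
  # +10 dB then -10 dB relative to the current RMS round-trips
  up <- set_level(w, 10, reference_rms = rms_of(w))
  back <- set_level(up, -10, reference_rms = rms_of(up))
  expect_equal(back$samples, w$samples, tolerance = 1e-9)
  a <- set_level(w, 5)
  b <- set_level(w, 0)
  expect_equal(rms_of(a) / rms_of(b), 10^(5 / 20), tolerance = 1e-12)
  expect_error(set_level(waveform(rep(0, 10), 100), 0), "silent")
  expect_error(set_level(w, 0, reference_rms = 0), "reference_rms")
})

test_that("windowed power difference vanishes for equalized full windows", {
  am <- set_level(apply_am(generate_gwn(1, 400), 5, 0, 1), 0)
  gw <- set_level(generate_gwn(2, 400), 0)
  expect_equal(windowed_power_difference(am, gw, 400), 0, tolerance = 1e-9)
})

test_that("120 Hz modulation leaves the initial 50 ms power unchanged on average", {
  d <- vapply(1:50, function(s) {
    am <- set_level(apply_am(generate_gwn(s, 400), 120, 0, 1), 0)
    gw <- set_level(generate_gwn(s + 500, 400), 0)
    windowed_power_difference(am, gw, 50)
  }, numeric(1))
  expect_lt(abs(mean(d)), 0.5)
})

test_that("5 Hz phase-0 modulation makes the stimulus initially softer", {
  am <- set_level(apply_am(generate_gwn(4, 400), 5, 0, 1), 0)
  gw <- set_level(generate_gwn(104, 400), 0)
  expect_lt(windowed_power_difference(am, gw, 50), 0)
})

test_that("phase power profile is periodic with extremes set by the envelope", {
  p0 <- phase_power_profile(5, c(0, 2 * pi), window_ms = 50, n_seeds = 5)
  expect_equal(p0$mean_db[1], p0$mean_db[2], tolerance = 1e-8)

  flat <- phase_power_profile(5, c(0, pi / 2, pi), window_ms = 50,
                              n_seeds = 3, depth = 0)
  expect_equal(flat$mean_db, rep(0, 3), tolerance = 1e-9)

  # the profile tracks the closed-form windowed envelope-squared integral
  phases <- (0:7) * pi / 4
  prof <- phase_power_profile(5, phases, window_ms = 50, n_seeds = 8)
  env2 <- function(ph, a, b) {
    stats::integrate(function(t) (1 - cos(2 * pi * 5 * t + ph))^2,
                     a, b)$value / (b - a)
  }
  pred_db <- vapply(phases, function(ph)
    10 * log10(env2(ph, 0, 0.05) / env2(ph, 0, 0.4)), numeric(1))
  expect_lt(max(abs(prof$mean_db - pred_db)), 0.5)
  expect_equal(which.min(prof$mean_db), which.min(pred_db))
  expect_equal(which.max(prof$mean_db), which.max(pred_db))
})

test_that("stimulus synthesis is reproducible and writes WAV plus sidecar", {
  spec <- stimulus_spec(kind = "AM", fm_hz = 5, phase_rad = 0,
                        duration_ms = 150, level_dba = 55, seed = 42)
  w1 <- synth_stimulus(spec)
  w2 <- synth_stimulus(spec)
  expect_identical(w1$samples, w2$samples)
  expect_equal(length(w1$samples), round(150 * 48828.125 / 1000))
  path <- withr::local_tempfile(fileext = ".wav")
  write_stimulus(w1, path, spec)
  expect_true(file.exists(path))
  side <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(side$kind, "AM")
  expect_equal(side$seed, 42)
})
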