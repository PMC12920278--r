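# Filtering, resampling, artifact rejection, pulse detection, beat cleaning.

test_that("band-pass removes DC and out-of-band tones, keeps in-band tones", {
  fs <- 128
  t <- seq(0, 30, by = 1 / fs)
  expect_lt(max(abs(bandpass_ppg(rep(2.5, length(t)), fs))), 1e-6)

  inband <- sin(2 * pi * 1.2 * t)
  y <- bandpass_ppg(inband, fs)
  mid <- seq(5 * fs, 25 * fs)                 # away from filter edges
  expect_lt(abs(max(y[mid]) - 1), 0.05)

  slow <- sin(2 * pi * 0.1 * t)
  ys <- bandpass_ppg(slow, fs)
  atten_db <- 20 * log10(max(abs(ys[mid])) / 1)
  expect_lt(atten_db, -20)

  expect_error(bandpass_ppg(inband, 40), "band-pass")
})

test_that("double filtering barely changes an in-band tone", {
  fs <- 128
  t <- seq(0, 30, by = 1 / fs)
  x <- sin(2 * pi * 1.5 * t)
  y1 <- bandpass_ppg(x, fs)
  y2 <- bandpass_ppg(y1, fs)
  mid <- seq(5 * fs, 25 * fs)
  expect_lt(abs(max(y2[mid]) / max(y1[mid]) - 1), 0.01)
})

test_that("resampling preserves identity, duration and waveform shape", {
  x <- rnorm(100)
  expect_identical(resample_signal(x, 128, 128), x)

  x60 <- rnorm(60 * 1024)
  y <- resample_signal(x60, 1024, 128)
  expect_length(y, 60 * 128)

  t <- seq(0, 60 - 1 / 1024, by = 1 / 1024)
  s <- sin(2 * pi * 2 * t)
  ds <- resample_signal(s, 1024, 128)
  t_out <- seq(0, 60 - 1 / 128, by = 1 / 128)
  ref <- sin(2 * pi * 2 * t_out)
  mid <- seq(128, length(ds) - 128)
  expect_gt(cor(ds[mid], ref[mid]), 0.999)
})

test_that("artifact rejection flags deviant samples per 60-s window", {
  fs <- 10
  # zero-variance window: threshold degenerates, nothing flagged
  expect_true(all(reject_artifacts(rep(1, 600), fs)))

  set.seed(42)
  x <- rnorm(600)
  x[100] <- 10
  v <- reject_artifacts(x, fs)
  expect_false(v[100])
  expect_gt(mean(v), 0.8)

  # clean synthetic pulse train: fewer than 20% of samples flagged
  rec <- small_recording()
  xf <- bandpass_ppg(rec$ppg$values, rec$ppg$fs)
  expect_lt(mean(!reject_artifacts(xf, rec$ppg$fs)), 0.2)
})

test_that("pulse detection recovers planted beats and amplitudes", {
  # clean 60 bpm pulse train for 60 s
  rec <- generate_recording(synth_config(duration_h = 1 / 60,
                                         event_rate_per_h = 0,
                                         base_pulse_rate = 60,
                                         noise_sd = 0, seed = 30))
  x <- bandpass_ppg(rec$ppg$values, 128)
  b <- detect_pulses(x, 128)
  expect_true(abs(nrow(b) - 60) <= 1)
  expect_lt(abs(mean(b$ppi, na.rm = TRUE) - 1.0), 0.02)
  expect_true(all(b$pwa > 0))
  expect_true(all(diff(b$peak_time) > 0))
  expect_true(all(b$trough_time < b$peak_time))

  expect_warning(empty <- detect_pulses(rep(0, 1280), 128), "no pulses")
  expect_equal(nrow(empty), 0)

  # planted per-beat amplitudes recovered (noise-free)
  rec2 <- generate_recording(synth_config(duration_h = 0.25, noise_sd = 0,
                                          seed = 31))
  x2 <- bandpass_ppg(rec2$ppg$values, 128)
  b2 <- detect_pulses(x2, 128)
  gt <- rec2$ground_truth
  idx <- findInterval(b2$peak_time, gt$beat_time)
  expect_gt(cor(b2$pwa, gt$pwa[idx]), 0.95)
  expect_lt(abs(nrow(b2) - nrow(gt)), 0.25 * 60 * 2)   # ±2 beats/min
})

test_that("beat cleaning masks implausible intervals and only those", {
  mk <- function(ppi_vec) {
    pt <- cumsum(c(0, ppi_vec))
    out <- tibble::tibble(peak_time = pt, trough_time = pt - 0.2,
                          pwa = rep(1, length(pt)),
                          ppi = c(NA, ppi_vec), valid = TRUE)
    class(out) <- c("oxi_beats", class(out))
    out
  }
  ok <- mk(rep(c(0.8, 0.81), 20))
  expect_identical(clean_beats(ok)$valid, ok$valid)

  bad <- mk(c(rep(0.8, 10), 3.0, rep(0.8, 10)))
  cleaned <- clean_beats(bad)
  expect_false(cleaned$valid[12])                 # the 3.0 s interval
  expect_equal(sum(!cleaned$valid), 1)

  jump <- mk(c(rep(1.0, 10), 0.5, rep(1.0, 10)))  # 50% jump from median
  expect_false(clean_beats(jump)$valid[12])

  expect_error(clean_beats(mk(numeric(0))[0, ]), "empty")
})

test_that("beat-series resampling hits the 4 Hz grid and conserves structure", {
  mk <- function(ppi_vec) {
    pt <- cumsum(c(0.3, ppi_vec))
    out <- tibble::tibble(peak_time = pt, trough_time = pt - 0.2,
                          pwa = rep(1, length(pt)),
                          ppi = c(NA, ppi_vec), valid = TRUE)
    class(out) <- c("oxi_beats", class(out))
    out
  }
  const <- mk(rep(1, 70))
  u <- resample_beat_series(const, "ppi", t_range = c(0, 60))
  expect_length(u$values, 240)
  expect_equal(u$fs, 4)
  expect_true(all(abs(u$values - 1) < 1e-6))

  # 0.1 Hz sinusoidal PPI modulation recovered as the dominant spectral peak
  n <- 120
  tt <- cumsum(rep(1, n))
  ppi_mod <- 1 + 0.1 * sin(2 * pi * 0.1 * tt)
  mod <- mk(ppi_mod)
  um <- resample_beat_series(mod, "ppi", t_range = c(1, 111))
  sp <- welch_psd(um$values - mean(um$values), fs = 4, nperseg = 240)
  f_peak <- sp$freq[which.max(sp$psd)]
  expect_lt(abs(f_peak - 0.1), 0.03)

  # mean conservation on clean input
  expect_lt(abs(mean(um$values) - mean(ppi_mod)) / mean(ppi_mod), 0.01)

  few <- mk(rep(1, 2))
  expect_error(resample_beat_series(few, "ppi"), "4 valid beats")
})

test_that("preprocessing a 1024 Hz recording reproduces the 128 Hz chain", {
  rec <- generate_recording(synth_config(duration_h = 1 / 12, ppg_fs = 1024,
                                         seed = 33))
  prep <- preprocess_recording(rec)
  expect_equal(prep$ppi_series$fs, 4)
  # ~60 bpm for 5 minutes
  expect_gt(sum(prep$beats$valid), 200)
  expect_lt(abs(mean(prep$beats$ppi[prep$beats$valid], na.rm = TRUE) - 1), 0.05)
})
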