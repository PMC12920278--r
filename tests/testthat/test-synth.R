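# Synthetic recording generator: scheduling, ground-truth consistency,
# arousal/desaturation phenomenology, cohort construction.

test_that("scheduled event count and reference AHI are exact", {
  rec0 <- generate_recording(synth_config(duration_h = 0.5,
                                          event_rate_per_h = 0, seed = 1))
  expect_equal(nrow(rec0$events), 0)
  expect_equal(rec0$reference_ahi, 0)

  rec <- generate_recording(synth_config(duration_h = 1,
                                         event_rate_per_h = 20, seed = 2))
  resp <- rec$events[rec$events$kind != "arousal", ]
  expect_equal(nrow(resp), 20)
  expect_equal(rec$reference_ahi, 20)
  # ground-truth consistency holds for arbitrary durations too
  rec2 <- generate_recording(synth_config(duration_h = 1.4,
                                          event_rate_per_h = 17, seed = 3))
  resp2 <- rec2$events[rec2$events$kind != "arousal", ]
  expect_equal(nrow(resp2) / rec2$recording_time_h, rec2$reference_ahi)
})

test_that("generator is deterministic and respects basic signal invariants", {
  cfg <- synth_config(duration_h = 0.25, event_rate_per_h = 16, seed = 11)
  a <- generate_recording(cfg)
  b <- generate_recording(cfg)
  expect_identical(a$ppg$values, b$ppg$values)
  expect_identical(a$spo2$values, b$spo2$values)
  expect_identical(a$events, b$events)

  expect_true(all(a$spo2$values >= 50 & a$spo2$values <= 100))
  # AC component: near-zero mean over 5-minute windows
  win <- matrix(a$ppg$values[1:(128 * 300 * 3)], ncol = 3)
  expect_true(all(abs(colMeans(win)) < 0.02))
  # annotation invariants
  resp <- a$events[a$events$kind != "arousal", ]
  expect_true(all(resp$duration >= 10))
  ar <- a$events[a$events$kind == "arousal", ]
  expect_true(all(ar$duration >= 3))
  expect_true(all(a$events$onset + a$events$duration <=
                    a$recording_time_h * 3600 + 1e-9))
})

test_that("every scheduled event has an arousal overlapping its final 5 s", {
  rec <- generate_recording(synth_config(duration_h = 1, event_rate_per_h = 25,
                                         seed = 4))
  resp <- rec$events[rec$events$kind != "arousal", ]
  ar <- rec$events[rec$events$kind == "arousal", ]
  for (i in seq_len(nrow(resp))) {
    tail_lo <- resp$onset[i] + resp$duration[i] - 5
    tail_hi <- resp$onset[i] + resp$duration[i]
    ov <- pmax(0, pmin(ar$onset + ar$duration, tail_hi) - pmax(ar$onset, tail_lo))
    expect_true(any(ov > 0))
  }
})

test_that("deeper configured desaturations lower the post-apnea SpO2 minimum", {
  mins <- sapply(c(2, 4, 6), function(depth) {
    rec <- generate_recording(synth_config(duration_h = 0.5,
                                           event_rate_per_h = 10,
                                           frac_apnea = 1,
                                           desat_depth_pct = depth, seed = 9))
    ev <- rec$events[rec$events$kind == "obstructive_apnea", ][1, ]
    t_sp <- (seq_along(rec$spo2$values) - 1) / rec$spo2$fs
    win <- t_sp >= ev$onset + ev$duration & t_sp <= ev$onset + ev$duration + 40
    min(rec$spo2$values[win])
  })
  expect_true(all(diff(mins) < 0))
})

test_that("arousal windows carry the configured PWA drop through the beat extractor", {
  rec <- generate_recording(synth_config(duration_h = 0.5,
                                         event_rate_per_h = 20,
                                         pwa_drop_frac = 0.5, seed = 21))
  beats <- preprocess_recording(rec)$beats
  ar <- rec$events[rec$events$kind == "arousal", ]
  in_ar <- vapply(beats$peak_time, function(t)
    any(t >= ar$onset & t <= ar$onset + ar$duration), logical(1))
  ratio <- mean(beats$pwa[in_ar & beats$valid]) /
    mean(beats$pwa[!in_ar & beats$valid])
  expect_gt(ratio, 0.4)
  expect_lt(ratio, 0.6)
})

test_that("an infeasible event rate is rejected with a clear error", {
  expect_error(generate_recording(synth_config(duration_h = 1,
                                               event_rate_per_h = 100,
                                               seed = 1)),
               "overlap")
})

test_that("severity bins follow largest-remainder rounding", {
  expect_equal(assign_severity_bins(90, c(0.122, 0.244, 0.356, 0.278)),
               c(11L, 22L, 32L, 25L))
  expect_equal(sum(assign_severity_bins(7, c(0.25, 0.25, 0.25, 0.25))), 7L)
  expect_error(assign_severity_bins(10, c(0.5, 0.2, 0.2, 0.2)), "sum to 1")
})

test_that("cohort generation is deterministic and honours the severity mix", {
  a <- generate_cohort(4, c(1, 0, 0, 0), duration_h = 0.25, seed = 5)
  expect_true(all(sapply(a, function(r) r$reference_ahi) < 5))

  b1 <- generate_cohort(6, c(0.1, 0.2, 0.4, 0.3), duration_h = 0.25, seed = 8)
  b2 <- generate_cohort(6, c(0.1, 0.2, 0.4, 0.3), duration_h = 0.25, seed = 8)
  expect_identical(lapply(b1, function(r) r$ppg$values),
                   lapply(b2, function(r) r$ppg$values))
  expect_identical(sapply(b1, function(r) r$reference_ahi),
                   sapply(b2, function(r) r$reference_ahi))

  expect_error(generate_cohort(1, c(1, 0, 0, 0)), "cross-validated")
})
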