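#' Configuration for the synthetic overnight-recording generator
#'
#' Bundles every knob of the synthetic polysomnography generator. The defaults
#' describe a plausible adult overnight study: a 60 bpm resting pulse with
#' respiratory modulation, apnea/hypopnea events at `event_rate_per_h` per
#' hour, each terminated by a cortical arousal that transiently drops pulse
#' wave amplitude (peripheral vasoconstriction) and shortens the pulse-to-pulse
#' interval (sympathetic tachycardia), and SpO2 desaturations that follow
#' apneas and the desaturating subset of hypopneas with a lag. The remaining
#' hypopneas are "arousal-only": they perturb PWA/PPI but leave SpO2 flat,
#' the phenotype that SpO2-only screening misses.
#'
#' @param duration_h Recording length in hours.
#' @param ppg_fs PPG sampling rate in Hz.
#' @param spo2_fs SpO2 sampling rate in Hz.
#' @param base_pulse_rate Baseline pulse rate in beats per minute.
#' @param base_pwa Baseline pulse wave amplitude in arbitrary units.
#' @param event_rate_per_h Scheduled apnea+hypopnea events per hour; this is
#'   the ground-truth AHI of the recording.
#' @param frac_apnea Fraction of events that are obstructive apneas (the rest
#'   are hypopneas).
#' @param frac_hypopnea_arousal_only Fraction of hypopneas with an arousal but
#'   no desaturation.
#' @param pwa_drop_frac Fractional PWA drop during the arousal window
#'   (0.4 means PWA falls to 60% of baseline).
#' @param ppi_shortening_frac Fractional PPI shortening during the arousal
#'   window.
#' @param desat_depth_pct SpO2 desaturation depth in percentage points for
#'   hypopneas; apneas desaturate 30% deeper and longer.
#' @param desat_lag_s Seconds from event end to the desaturation nadir.
#' @param noise_sd Additive white-noise SD on the PPG waveform, in amplitude
#'   units.
#' @param seed Integer seed; the generator is fully deterministic given the
#'   configuration.
#' @return A list of class `oxi_synth_config`.
#' @export
#' @examples
#' cfg <- synth_config(duration_h = 0.5, event_rate_per_h = 10)
#' rec <- generate_recording(cfg)
#' rec$reference_ahi
synth_config <- function(duration_h = 2,
                         ppg_fs = 128,
                         spo2_fs = 16,
                         base_pulse_rate = 60,
                         base_pwa = 1,
                         event_rate_per_h = 20,
                         frac_apnea = 0.15,
                         frac_hypopnea_arousal_only = 0.3,
                         pwa_drop_frac = 0.4,
                         ppi_shortening_frac = 0.15,
                         desat_depth_pct = 4,
                         desat_lag_s = 15,
                         noise_sd = 0.02,
                         seed = 1L) {
  assert_positive(duration_h, "duration_h")
  assert_positive(ppg_fs, "ppg_fs")
  assert_positive(spo2_fs, "spo2_fs")
  assert_positive(base_pulse_rate, "base_pulse_rate")
  assert_positive(base_pwa, "base_pwa")
  if (event_rate_per_h < 0) stop("`event_rate_per_h` must be >= 0")
  assert_fraction(frac_apnea, "frac_apnea")
  assert_fraction(frac_hypopnea_arousal_only, "frac_hypopnea_arousal_only")
  assert_fraction(pwa_drop_frac, "pwa_drop_frac")
  assert_fraction(ppi_shortening_frac, "ppi_shortening_frac")
  if (desat_depth_pct < 0) stop("`desat_depth_pct` must be >= 0")
  assert_positive(desat_lag_s, "desat_lag_s")
  if (noise_sd < 0) stop("`noise_sd` must be >= 0")
  structure(
    list(duration_h = duration_h, ppg_fs = ppg_fs, spo2_fs = spo2_fs,
         base_pulse_rate = base_pulse_rate, base_pwa = base_pwa,
         event_rate_per_h = event_rate_per_h, frac_apnea = frac_apnea,
         frac_hypopnea_arousal_only = frac_hypopnea_arousal_only,
         pwa_drop_frac = pwa_drop_frac,
         ppi_shortening_frac = ppi_shortening_frac,
         desat_depth_pct = desat_depth_pct, desat_lag_s = desat_lag_s,
         noise_sd = noise_sd, seed = as.integer(seed)),
    class = "oxi_synth_config"
  )
}

# Schedule apnea/hypopnea events evenly spaced with jittered gaps so the
# scheduled count (hence the reference AHI) is exact. Durations follow the
# AASM floor of 10 s. Returns the event table plus arousal annotations.
schedule_events <- function(config) {
  total_s <- config$duration_h * 3600
  n_events <- round(config$event_rate_per_h * config$duration_h)
  if (n_events == 0) {
    return(tibble::tibble(kind = character(), onset = numeric(),
                          duration = numeric(), desaturating = logical()))
  }
  spacing <- total_s / n_events
  if (spacing < 45) {
    stop("event_rate_per_h too high: scheduled events would overlap ",
         "(mean gap ", round(spacing, 1), " s < 45 s)", call. = FALSE)
  }
  centre <- (seq_len(n_events) - 0.5) * spacing
  jitter <- runif(n_events, -0.1, 0.1) * spacing
  duration <- runif(n_events, 12, 28)
  onset <- pmax(0, pmin(centre + jitter - duration / 2,
                        total_s - duration - 12))

  n_apnea <- round(config$frac_apnea * n_events)
  kind <- rep("hypopnea", n_events)
  if (n_apnea > 0) kind[sample.int(n_events, n_apnea)] <- "obstructive_apnea"
  hyp_idx <- which(kind == "hypopnea")
  n_arousal_only <- round(config$frac_hypopnea_arousal_only * length(hyp_idx))
  desaturating <- rep(TRUE, n_events)
  if (n_arousal_only > 0) {
    desaturating[sample(hyp_idx, n_arousal_only)] <- FALSE
  }
  tibble::tibble(kind = kind, onset = onset, duration = duration,
                 desaturating = desaturating)
}

# Arousal response multiplier at arbitrary times: factor `1 - drop` inside
# each arousal window, exponential recovery (tau = 15 s) afterwards.
arousal_factor <- function(t, arousal_on, arousal_off, drop, tau = 15) {
  f <- rep(1, length(t))
  if (length(arousal_on) == 0L || drop <= 0) return(f)
  idx <- findInterval(t, arousal_on)
  has <- idx >= 1L
  if (!any(has)) return(f)
  on <- arousal_on[idx[has]]
  off <- arousal_off[idx[has]]
  ti <- t[has]
  fac <- ifelse(ti <= off, 1 - drop,
                1 - drop * exp(-(ti - off) / tau))
  f[has] <- fac
  f
}

# Periodic pulse waveform over phase [0, 1): fast half-cosine systolic rise
# to the peak at phase `a`, slow half-cosine decay back to the trough, plus a
# small zero-mean dicrotic bump on the descending limb. Trough -1 at phase 0,
# peak +1 at phase `a`, zero mean over a cycle; the crest factor (~1.4)
# matches band-passed finger PPG, for which the 1.5-SD artifact rule leaves
# ordinary systolic peaks unflagged.
pulse_waveform <- function(phi, a = 0.2, squash = 1.2) {
  w <- pulse_waveform_base(phi, a)
  # soft-clip the extremes: rounds systole/diastole like a perfused finger
  # pulse and keeps ordinary peaks inside the 1.5-SD artifact threshold
  w <- tanh(squash * w) / tanh(squash)
  ref <- tanh(squash * pulse_waveform_base((seq_len(1024) - 0.5) / 1024, a)) /
    tanh(squash)
  w - mean(ref)
}

pulse_waveform_base <- function(phi, a = 0.2) {
  w <- ifelse(phi < a, -cos(pi * phi / a), cos(pi * (phi - a) / (1 - a)))
  dic <- phi >= 0.4 & phi < 0.7
  w[dic] <- w[dic] + 0.15 * sin(2 * pi * (phi[dic] - 0.4) / 0.3)
  w
}

#' Generate one synthetic overnight recording
#'
#' Builds a PPG waveform as a train of asymmetric pulse wavelets with planted
#' beat-to-beat amplitude (PWA) and interval (PPI) modulation, an SpO2 trace
#' with post-event desaturations, and the matching apnea/hypopnea/arousal
#' annotations. Every event carries a terminating arousal; during the arousal
#' window PWA is multiplied by `1 - pwa_drop_frac` and PPI by
#' `1 - ppi_shortening_frac`, both recovering exponentially over ~15 s.
#' Apneas and the desaturating subset of hypopneas are followed by an SpO2
#' dip of `desat_depth_pct` (apneas 30% deeper) with its nadir `desat_lag_s`
#' seconds after event end.
#'
#' The returned object records the planted per-beat ground truth
#' (`$ground_truth`: beat time, PPI, PWA, arousal state) so downstream
#' detectors can be validated against what was actually generated.
#'
#' @param config A [synth_config()] object.
#' @param subject_id Subject identifier string.
#' @param comorbidity Logical comorbidity flag carried into the metadata.
#' @return A list of class `oxi_recording` with elements `ppg` and `spo2`
#'   (each `list(values, fs)`), `events` (tibble: kind, onset, duration),
#'   `recording_time_h`, `reference_ahi`, `comorbidity`, `ground_truth`.
#' @export
generate_recording <- function(config, subject_id = "S01",
                               comorbidity = FALSE) {
  stopifnot(inherits(config, "oxi_synth_config"))
  set.seed(config$seed)
  total_s <- config$duration_h * 3600

  sched <- schedule_events(config)
  resp_events <- sched[, c("kind", "onset", "duration")]
  # every scheduled event ends in an arousal overlapping its final seconds
  if (nrow(sched) > 0) {
    arousal <- tibble::tibble(
      kind = "arousal",
      onset = sched$onset + sched$duration - 2,
      duration = 8
    )
    arousal$duration <- pmin(arousal$duration, total_s - arousal$onset)
    events <- dplyr::bind_rows(resp_events, arousal)
  } else {
    events <- resp_events
  }
  events <- dplyr::arrange(events, .data$onset)

  ar_on <- sort(sched$onset + sched$duration - 2)
  ar_off <- ar_on + 8

  # --- beat schedule ------------------------------------------------------
  base_ppi <- 60 / config$base_pulse_rate
  n_max <- ceiling(total_s / (base_ppi * (1 - config$ppi_shortening_frac) * 0.8)) + 4L
  beat_t <- numeric(n_max)
  ppi_v <- numeric(n_max)
  pwa_v <- numeric(n_max)
  resp_f <- 0.25                        # respiratory sinus modulation, Hz
  pwa_mod_f <- 0.1                      # slow vasomotor PWA oscillation, Hz
  t <- 0
  i <- 0L
  while (t < total_s) {
    i <- i + 1L
    fac_ppi <- arousal_factor(t, ar_on, ar_off, config$ppi_shortening_frac)
    fac_pwa <- arousal_factor(t, ar_on, ar_off, config$pwa_drop_frac)
    ppi <- base_ppi * (1 + 0.02 * sin(2 * pi * resp_f * t)) * fac_ppi *
      (1 + rnorm(1, 0, 0.01))
    pwa <- config$base_pwa * (1 + 0.05 * sin(2 * pi * pwa_mod_f * t)) *
      fac_pwa * exp(rnorm(1, 0, 0.04))
    beat_t[i] <- t
    ppi_v[i] <- ppi
    pwa_v[i] <- pwa
    t <- t + ppi
  }
  n_beats <- i
  beat_t <- beat_t[seq_len(n_beats)]
  ppi_v <- ppi_v[seq_len(n_beats)]
  pwa_v <- pwa_v[seq_len(n_beats)]

  # --- PPG waveform (phase-based synthesis) -------------------------------
  # Each sample gets the phase of the beat cycle it falls in; the amplitude
  # of cycle i is pwa_i / 2 so the planted peak-to-trough amplitude equals
  # the planted PWA.
  n_ppg <- round(total_s * config$ppg_fs)
  ts <- (seq_len(n_ppg) - 1) / config$ppg_fs
  j <- findInterval(ts, beat_t)
  j[j < 1L] <- 1L
  phi <- pmin((ts - beat_t[j]) / ppi_v[j], 0.999)
  ppg <- (pwa_v[j] / 2) * pulse_waveform(phi)
  if (config$noise_sd > 0) ppg <- ppg + rnorm(n_ppg, 0, config$noise_sd)
  # keep only the AC component: remove a 2-s moving-average baseline
  ppg <- ppg - runmean(ppg, round(2 * config$ppg_fs))

  # --- SpO2 trace ---------------------------------------------------------
  n_sp <- round(total_s * config$spo2_fs)
  t_sp <- (seq_len(n_sp) - 1) / config$spo2_fs
  # red-noise baseline wander around 97%
  ar <- numeric(n_sp)
  innov <- rnorm(n_sp)
  phi <- 0.999
  ar <- stats::filter(innov, phi, method = "recursive")
  ar <- as.numeric(ar) / sd(as.numeric(ar)) * 0.3
  spo2 <- 97 + ar
  if (nrow(sched) > 0 && config$desat_depth_pct > 0) {
    desat <- sched[sched$desaturating, , drop = FALSE]
    for (j in seq_len(nrow(desat))) {
      is_apnea <- desat$kind[j] == "obstructive_apnea"
      depth <- config$desat_depth_pct * (if (is_apnea) 1.3 else 1)
      width <- 8 * (if (is_apnea) 1.3 else 1)
      nadir <- desat$onset[j] + desat$duration[j] + config$desat_lag_s
      win <- which(abs(t_sp - nadir) < 4 * width)
      spo2[win] <- spo2[win] - depth * exp(-0.5 * ((t_sp[win] - nadir) / width)^2)
    }
  }
  spo2 <- pmin(pmax(spo2, 50), 100)

  reference_ahi <- nrow(resp_events) / config$duration_h

  structure(
    list(
      subject_id = subject_id,
      ppg = list(values = ppg, fs = config$ppg_fs),
      spo2 = list(values = spo2, fs = config$spo2_fs),
      events = tibble::as_tibble(events),
      recording_time_h = config$duration_h,
      reference_ahi = reference_ahi,
      comorbidity = isTRUE(comorbidity),
      config = config,
      ground_truth = tibble::tibble(
        beat_time = beat_t, peak_time = beat_t + 0.25 * ppi_v,
        ppi = ppi_v, pwa = pwa_v,
        in_arousal = arousal_in_window(beat_t, ar_on, ar_off)
      )
    ),
    class = "oxi_recording"
  )
}

arousal_in_window <- function(t, on, off) {
  if (length(on) == 0L) return(rep(FALSE, length(t)))
  idx <- findInterval(t, on)
  has <- idx >= 1L
  res <- rep(FALSE, length(t))
  res[has] <- t[has] <= off[idx[has]]
  res
}

# centred moving average with edge shrinkage
runmean <- function(x, k) {
  k <- max(1L, as.integer(k))
  cs <- cumsum(c(0, x))
  n <- length(x)
  half <- k %/% 2L
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' @export
print.oxi_recording <- function(x, ...) {
  cat(sprintf(
    "<oxi_recording> %s: %.2f h, PPG %g Hz, SpO2 %g Hz, %d events, reference AHI %.1f\n",
    x$subject_id, x$recording_time_h, x$ppg$fs, x$spo2$fs,
    sum(x$events$kind != "arousal"), x$reference_ahi))
  invisible(x)
}

#' Allocate cohort sizes to AHI severity bins by largest-remainder rounding
#'
#' @param n Number of subjects.
#' @param severity_mix Fractions over the four severity bins
#'   (AHI < 5, 5-15, 15-30, > 30); must sum to 1.
#' @return Integer vector of length 4 summing to `n`.
#' @export
assign_severity_bins <- function(n, severity_mix) {
  stopifnot(length(severity_mix) == 4, all(severity_mix >= 0))
  if (abs(sum(severity_mix) - 1) > 1e-8) {
    stop("`severity_mix` fractions must sum to 1", call. = FALSE)
  }
  target <- n * severity_mix
  counts <- floor(target)
  rem <- n - sum(counts)
  if (rem > 0) {
    frac <- target - counts
    add <- order(frac, decreasing = TRUE)[seq_len(rem)]
    counts[add] <- counts[add] + 1
  }
  as.integer(counts)
}

#' Generate a synthetic cohort spanning the OSA severity spectrum
#'
#' Subjects are allocated to the four AHI severity bins (no OSA: AHI < 5,
#' mild: 5-15, moderate: 15-30, severe: > 30) by largest-remainder rounding of
#' `severity_mix`, and each subject's ground-truth AHI is drawn uniformly
#' within its bin. Baseline pulse rate varies across subjects; roughly half
#' carry a comorbidity flag.
#'
#' @param n_subjects Number of subjects (>= 2, otherwise cross-validation is
#'   impossible).
#' @param severity_mix Fractions over the four severity bins, summing to 1.
#' @param duration_h Recording length per subject, hours.
#' @param seed Integer seed; fixed seed reproduces the cohort exactly.
#' @param base_config Template [synth_config()] supplying all other generator
#'   parameters.
#' @return List of `oxi_recording` objects.
#' @export
generate_cohort <- function(n_subjects,
                            severity_mix = c(0.122, 0.244, 0.356, 0.278),
                            duration_h = 2,
                            seed = 1L,
                            base_config = synth_config()) {
  if (n_subjects < 2) {
    stop("`n_subjects` must be >= 2 (a single subject cannot be cross-validated)",
         call. = FALSE)
  }
  counts <- assign_severity_bins(n_subjects, severity_mix)
  bin_lo <- c(0.5, 5, 15, 30.5)
  bin_hi <- c(4.5, 14.9, 30, 50)
  bins <- rep(seq_len(4L), counts)

  set.seed(derive_seed(seed, "cohort"))
  ahi <- runif(n_subjects, bin_lo[bins], bin_hi[bins])
  pulse <- runif(n_subjects, 55, 75)
  comorb <- runif(n_subjects) < 0.5
  subj_seeds <- sample.int(2147480000L, n_subjects)

  lapply(seq_len(n_subjects), function(i) {
    cfg <- base_config
    cfg$duration_h <- duration_h
    cfg$event_rate_per_h <- ahi[i]
    cfg$base_pulse_rate <- pulse[i]
    cfg$seed <- subj_seeds[i]
    generate_recording(cfg, subject_id = sprintf("S%02d", i),
                       comorbidity = comorb[i])
  })
}
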