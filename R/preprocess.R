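# Preprocessing: band-pass filtering, resampling, artifact rejection, pulse
# detection and beat cleaning. The end product per recording is a cleaned
# beat series (PPI/PWA) and uniformly sampled 4 Hz PPI/PWA series.

#' Zero-phase Butterworth band-pass for PPG
#'
#' Applies a forward-backward (zero-phase) Butterworth band-pass, removing the
#' DC/baseline component below `low` and high-frequency noise above `high`.
#' Zero-phase filtering preserves systolic peak timing.
#'
#' @param x PPG waveform samples.
#' @param fs Sampling rate, Hz.
#' @param low,high Passband edges, Hz.
#' @param order Filter order (applied twice by filtfilt).
#' @return Filtered waveform of the same length.
#' @export
bandpass_ppg <- function(x, fs, low = 0.7, high = 20, order = 4) {
  assert_positive(fs, "fs")
  if (fs <= 2 * high) {
    stop("sampling rate ", fs, " Hz cannot support a band-pass up to ", high,
         " Hz (need fs > ", 2 * high, " Hz)", call. = FALSE)
  }
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  # odd-reflection padding suppresses the start/end transients of the
  # forward-backward pass
  n <- length(x)
  pad <- min(n - 1L, round(10 * fs))
  xp <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
  y <- as.numeric(signal::filtfilt(bf, xp))
  y[(pad + 1):(pad + n)]
}

#' Anti-aliased sampling-rate conversion
#'
#' Polyphase FIR resampling between two integer sampling rates (e.g. the
#' native 1024 Hz PPG down to 128 Hz). Duration is preserved to within one
#' output sample.
#'
#' @param x Waveform samples.
#' @param fs_in,fs_out Input and output sampling rates, Hz (integers).
#' @return Resampled waveform.
#' @export
resample_signal <- function(x, fs_in, fs_out) {
  assert_positive(fs_in, "fs_in")
  assert_positive(fs_out, "fs_out")
  if (fs_in == fs_out) return(x)
  if (fs_in != round(fs_in) || fs_out != round(fs_out)) {
    stop("resample_signal requires integer sampling rates", call. = FALSE)
  }
  g <- pracma::gcd(as.integer(fs_in), as.integer(fs_out))
  p <- as.integer(fs_out / g)
  q <- as.integer(fs_in / g)
  n <- length(x)
  n_out <- round(n * fs_out / fs_in)

  # upsample by zero-stuffing, windowed-sinc low-pass at the tighter of the
  # two Nyquist limits, then decimate
  if (p > 1L) {
    xu <- numeric(n * p)
    xu[seq(1L, by = p, length.out = n)] <- x
  } else {
    xu <- x
  }
  n_up <- length(xu)
  n_taps <- 16L * max(p, q)                   # even; group delay n_taps/2
  wc <- min(1 / p, 1 / q)
  b <- as.numeric(signal::fir1(n_taps, wc)) * p
  pad <- min(n_up - 1L, n_taps)
  xp <- c(2 * xu[1] - xu[(pad + 1):2], xu, 2 * xu[n_up] - xu[(n_up - 1):(n_up - pad)])
  yf <- stats::convolve(xp, rev(b), type = "open")
  y <- yf[(pad + n_taps / 2 + 1):(pad + n_taps / 2 + n_up)]
  out <- y[seq(1L, by = q, length.out = ceiling(n_up / q))]
  length(out) <- min(length(out), n_out)
  if (length(out) < n_out) {
    out <- c(out, rep(out[length(out)], n_out - length(out)))
  }
  as.numeric(out)
}

#' Flag artifact samples in 60-second windows
#'
#' Within each non-overlapping window, samples deviating from the window mean
#' by more than `k` window standard deviations are flagged invalid. A
#' zero-variance window flags nothing (the threshold degenerates). Beats whose
#' peak or trough lands on a flagged sample are dropped downstream.
#'
#' @param x Waveform samples.
#' @param fs Sampling rate, Hz.
#' @param window_s Window length, seconds.
#' @param k Threshold in window standard deviations.
#' @return Logical vector, `TRUE` for valid samples.
#' @export
reject_artifacts <- function(x, fs, window_s = 60, k = 1.5) {
  wlen <- round(window_s * fs)
  if (wlen < 2) stop("window too short: need window_s * fs >= 2", call. = FALSE)
  n <- length(x)
  valid <- rep(TRUE, n)
  starts <- seq(1L, n, by = wlen)
  for (s in starts) {
    e <- min(s + wlen - 1L, n)
    w <- x[s:e]
    sdw <- sd(w)
    if (!is.finite(sdw) || sdw == 0) next
    valid[s:e] <- abs(w - mean(w)) <= k * sdw
  }
  valid
}

#' Detect systolic pulses and derive the beat series
#'
#' Systolic peaks are local maxima separated by at least `60/max_rate`
#' seconds whose height exceeds an adaptive threshold (a fraction of the
#' rolling signal amplitude, so the detector follows pulse-amplitude drops).
#' Each peak is paired with the preceding local minimum as its diastolic
#' trough. The pulse-to-pulse interval (PPI) is the time between successive
#' systolic peaks; the pulse wave amplitude (PWA) is the peak-to-trough
#' amplitude difference.
#'
#' @param x Band-passed PPG waveform.
#' @param fs Sampling rate, Hz.
#' @param min_rate,max_rate Physiological pulse-rate bounds, bpm.
#' @param valid Optional per-sample validity mask from [reject_artifacts()];
#'   beats with peak or trough on an invalid sample are marked invalid.
#' @param prominence Fraction of the rolling amplitude a peak must exceed.
#' @return A tibble of class `oxi_beats` with columns `peak_time`,
#'   `trough_time`, `pwa`, `ppi` (interval ending at this peak; `NA` for the
#'   first beat) and `valid`.
#' @export
detect_pulses <- function(x, fs, min_rate = 30, max_rate = 180, valid = NULL,
                          prominence = 0.3) {
  min_dist <- round(fs * 60 / max_rate)
  empty <- tibble::tibble(peak_time = numeric(), trough_time = numeric(),
                          pwa = numeric(), ppi = numeric(), valid = logical())
  class(empty) <- c("oxi_beats", class(empty))

  # adaptive height threshold from the rolling amplitude (10-s blocks)
  blk <- max(1L, round(10 * fs))
  n <- length(x)
  nblk <- ceiling(n / blk)
  blk_id <- rep(seq_len(nblk), each = blk)[seq_len(n)]
  blk_max <- tapply(x, blk_id, max)
  thr <- prominence * pmax(blk_max, 0)[blk_id]

  pk <- pracma::findpeaks(x, minpeakdistance = max(min_dist, 1L), npeaks = 0)
  if (is.null(pk) || nrow(pk) < 2) {
    if (!is.null(pk) && nrow(pk) == 1) {
      warning("fewer than 2 pulses detected; returning empty beat series")
      return(empty)
    }
    warning("no pulses detected; returning empty beat series")
    return(empty)
  }
  idx <- sort(pk[, 2])
  idx <- idx[x[idx] > thr[idx] & x[idx] > 0]
  if (length(idx) < 2) {
    warning("fewer than 2 pulses detected; returning empty beat series")
    return(empty)
  }

  # preceding trough: minimum between the previous peak (or 0.7 s back) and
  # this peak
  lookback <- round(0.7 * fs)
  tr_idx <- integer(length(idx))
  for (i in seq_along(idx)) {
    lo <- if (i == 1) max(1L, idx[i] - lookback) else max(idx[i - 1], idx[i] - lookback)
    seg <- lo:(idx[i] - 1L)
    if (length(seg) == 0L) seg <- lo
    tr_idx[i] <- seg[which.min(x[seg])]
  }

  pwa <- x[idx] - x[tr_idx]
  ok <- pwa > 0
  idx <- idx[ok]; tr_idx <- tr_idx[ok]; pwa <- pwa[ok]
  if (length(idx) < 2) {
    warning("fewer than 2 pulses detected; returning empty beat series")
    return(empty)
  }
  # refine peak times to the centroid of the systolic crest (samples within
  # 90% of the local peak height above the trough); the raw argmax wanders
  # across the rounded crest under noise, which would inflate PPI jitter
  half <- round(0.15 * fs)
  peak_time <- vapply(seq_along(idx), function(i) {
    lo <- max(tr_idx[i], idx[i] - half)
    hi <- min(if (i < length(idx)) tr_idx[i + 1] else length(x), idx[i] + half)
    seg <- lo:hi
    base <- x[tr_idx[i]]
    keep <- seg[x[seg] >= base + 0.9 * (x[idx[i]] - base)]
    (mean(keep) - 1) / fs
  }, numeric(1))
  beat_valid <- rep(TRUE, length(idx))
  if (!is.null(valid)) beat_valid <- valid[idx] & valid[tr_idx]
  mono <- c(TRUE, diff(peak_time) > 0)
  idx <- idx[mono]; tr_idx <- tr_idx[mono]; pwa <- pwa[mono]
  peak_time <- peak_time[mono]; beat_valid <- beat_valid[mono]

  out <- tibble::tibble(
    peak_time = peak_time,
    trough_time = (tr_idx - 1) / fs,
    pwa = pwa,
    ppi = c(NA_real_, diff(peak_time)),
    valid = beat_valid
  )
  class(out) <- c("oxi_beats", class(out))
  out
}

#' Mask artifactual beats to leave NN (normal-to-normal) intervals
#'
#' A beat is invalidated when its PPI falls outside `[min_ppi, max_ppi]`
#' seconds or differs by more than `max_jump` (fraction) from the median of
#' the five preceding valid PPIs. No interpolation happens here; invalid
#' beats are simply masked.
#'
#' @param beats An `oxi_beats` tibble.
#' @param min_ppi,max_ppi Physiological PPI bounds, seconds.
#' @param max_jump Maximum allowed fractional deviation from the running
#'   median of the 5 preceding valid PPIs.
#' @return The beat series with an updated `valid` mask; attribute
#'   `low_quality` is `TRUE` when more than half the beats are invalid.
#' @export
clean_beats <- function(beats, min_ppi = 0.33, max_ppi = 2.0, max_jump = 0.3) {
  if (nrow(beats) == 0) stop("empty beat series", call. = FALSE)
  valid <- beats$valid
  ppi <- beats$ppi
  recent <- numeric(0)
  for (i in seq_len(nrow(beats))) {
    if (!valid[i]) next
    if (is.na(ppi[i])) next                      # first beat has no interval
    bad <- ppi[i] < min_ppi || ppi[i] > max_ppi
    if (!bad && length(recent) > 0) {
      m <- median(recent)
      bad <- abs(ppi[i] - m) / m > max_jump
    }
    if (bad) {
      valid[i] <- FALSE
    } else {
      recent <- c(recent, ppi[i])
      if (length(recent) > 5) recent <- recent[-1]
    }
  }
  beats$valid <- valid
  attr(beats, "low_quality") <- mean(!valid) > 0.5
  beats
}

#' Resample a beat-indexed sequence to a uniform 4 Hz series
#'
#' Cubic-spline interpolation of PPI or PWA against the systolic peak times,
#' evaluated on a uniform grid. Gaps left by invalid beats are bridged by the
#' interpolant.
#'
#' @param beats An `oxi_beats` tibble (after [clean_beats()]).
#' @param field `"ppi"` or `"pwa"`.
#' @param fs_out Output rate, Hz.
#' @param t_range Length-2 numeric: grid start and end (seconds). Defaults to
#'   the span of valid peak times.
#' @return A list of class `oxi_uniform` with `values`, `fs`, `t0`.
#' @export
resample_beat_series <- function(beats, field = c("ppi", "pwa"), fs_out = 4,
                                 t_range = NULL) {
  field <- match.arg(field)
  keep <- beats$valid & !is.na(beats[[field]])
  tt <- beats$peak_time[keep]
  vv <- beats[[field]][keep]
  if (length(tt) < 4) {
    stop("fewer than 4 valid beats: segment unusable for resampling",
         call. = FALSE)
  }
  if (is.null(t_range)) t_range <- range(tt)
  # half-open grid [t0, t1): a 60-s span at 4 Hz gives exactly 240 samples
  n_out <- max(1L, floor((t_range[2] - t_range[1]) * fs_out + 1e-9))
  grid <- t_range[1] + (seq_len(n_out) - 1L) / fs_out
  sf <- splinefun(tt, vv, method = "natural")
  structure(list(values = sf(grid), fs = fs_out, t0 = grid[1]),
            class = "oxi_uniform")
}

#' Run the full preprocessing chain on one recording
#'
#' Resamples PPG to `target_fs`, band-pass filters it, flags artifact samples,
#' detects pulses, masks artifactual beats, and builds recording-wide 4 Hz
#' PPI and PWA series. SpO2 is used at its native resolution.
#'
#' @param recording An `oxi_recording`.
#' @param target_fs PPG analysis rate, Hz.
#' @param low,high Band-pass edges, Hz.
#' @param artifact_k Artifact threshold in window SDs.
#' @return A list of class `oxi_prep`: `beats`, `ppi_series`, `pwa_series`
#'   (4 Hz, t0 = 0), `spo2`, `events`, metadata fields.
#' @export
preprocess_recording <- function(recording, target_fs = 128, low = 0.7,
                                 high = 20, artifact_k = 1.5) {
  stopifnot(inherits(recording, "oxi_recording"))
  x <- recording$ppg$values
  fs <- recording$ppg$fs
  if (fs != target_fs) {
    x <- resample_signal(x, fs, target_fs)
    fs <- target_fs
  }
  x <- bandpass_ppg(x, fs, low = low, high = high)
  valid <- reject_artifacts(x, fs, k = artifact_k)
  beats <- detect_pulses(x, fs, valid = valid)
  beats <- clean_beats(beats)
  dur_s <- recording$recording_time_h * 3600
  ppi_series <- resample_beat_series(beats, "ppi", t_range = c(0, dur_s))
  pwa_series <- resample_beat_series(beats, "pwa", t_range = c(0, dur_s))
  structure(
    list(subject_id = recording$subject_id,
         beats = beats,
         ppi_series = ppi_series,
         pwa_series = pwa_series,
         spo2 = recording$spo2,
         events = recording$events,
         recording_time_h = recording$recording_time_h,
         reference_ahi = recording$reference_ahi,
         comorbidity = recording$comorbidity),
    class = "oxi_prep"
  )
}
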