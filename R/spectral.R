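# Welch power spectral density and band-power features for the 4 Hz PPI/PWA
# series.

hann_window <- function(n) 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))

detrend_linear <- function(x) {
  t <- seq_along(x)
  stats::lsfit(t, x)$residuals
}

#' Welch power spectral density
#'
#' Hann-windowed, linearly detrended sub-windows with 50% overlap, averaged
#' one-sided periodograms (density scaling, units squared per Hz). With the
#' default 120-sample sub-window a 240-sample (60 s at 4 Hz) segment yields
#' three averaged periodograms.
#'
#' @param x Uniformly sampled series (numeric or `oxi_uniform`).
#' @param fs Sampling rate, Hz (taken from `x` when it is an `oxi_uniform`).
#' @param nperseg Sub-window length, samples.
#' @param overlap Fractional sub-window overlap.
#' @return List with `freq` (Hz) and `psd`.
#' @export
welch_psd <- function(x, fs = NULL, nperseg = 120, overlap = 0.5) {
  if (inherits(x, "oxi_uniform")) {
    fs <- x$fs
    x <- x$values
  }
  stopifnot(!is.null(fs))
  n <- length(x)
  nperseg <- min(nperseg, n)
  step <- max(1L, round(nperseg * (1 - overlap)))
  starts <- seq(1L, n - nperseg + 1L, by = step)
  w <- hann_window(nperseg)
  scale <- fs * sum(w^2)
  acc <- NULL
  for (s in starts) {
    seg <- detrend_linear(x[s:(s + nperseg - 1L)]) * w
    p <- Mod(fft(seg))^2 / scale
    acc <- if (is.null(acc)) p else acc + p
  }
  p <- acc / length(starts)
  nfreq <- floor(nperseg / 2) + 1L
  p <- p[seq_len(nfreq)]
  # one-sided: double all but DC (and Nyquist when nperseg is even)
  dbl <- seq(2L, nfreq - (1 - nperseg %% 2))
  p[dbl] <- 2 * p[dbl]
  list(freq = (seq_len(nfreq) - 1) * fs / nperseg, psd = p)
}

# Trapezoidal integral of the PSD over [lo, hi], with PSD values interpolated
# at the band edges so narrow bands below the frequency resolution still
# integrate to a finite (resolution-limited) power.
band_power <- function(freq, psd, lo, hi) {
  hi <- min(hi, max(freq))
  lo <- max(lo, min(freq))
  if (hi <= lo) return(0)
  inner <- freq[freq > lo & freq < hi]
  grid <- unique(sort(c(lo, inner, hi)))
  vals <- approx(freq, psd, xout = grid)$y
  pracma::trapz(grid, vals)
}

#' Default HRV band definition
#'
#' Very-low (0.003-0.04 Hz), low (0.04-0.15 Hz) and high (0.15-0.4 Hz)
#' frequency bands of pulse-rate and pulse-amplitude variability spectra.
#'
#' @return Named list of `c(lo, hi)` pairs.
#' @export
hrv_bands <- function() {
  list(VLF = c(0.003, 0.04), LF = c(0.04, 0.15), HF = c(0.15, 0.4))
}

#' Band powers and normalized units from a Welch PSD
#'
#' @param u Uniform series (`oxi_uniform` or numeric with `fs`).
#' @param fs Sampling rate when `u` is numeric.
#' @param bands Band definition, see [hrv_bands()].
#' @param nperseg Welch sub-window, samples.
#' @return Named list: `VLF`, `LF`, `HF`, `LFnu`, `HFnu`, `LF_HF`. Normalized
#'   units satisfy `LFnu + HFnu = 1`; all three are `NA` when `LF + HF = 0`.
#' @export
band_powers <- function(u, fs = NULL, bands = hrv_bands(), nperseg = 120) {
  if (inherits(u, "oxi_uniform")) {
    fs <- u$fs
    u <- u$values
  }
  if (sd(u) == 0) {
    return(list(VLF = 0, LF = 0, HF = 0, LFnu = NA_real_, HFnu = NA_real_,
                LF_HF = NA_real_))
  }
  w <- welch_psd(u, fs = fs, nperseg = nperseg)
  vlf <- band_power(w$freq, w$psd, bands$VLF[1], bands$VLF[2])
  lf <- band_power(w$freq, w$psd, bands$LF[1], bands$LF[2])
  hf <- band_power(w$freq, w$psd, bands$HF[1], bands$HF[2])
  tot <- lf + hf
  if (tot > 0) {
    lfnu <- lf / tot; hfnu <- hf / tot
    ratio <- if (hf > 0) lf / hf else NA_real_
  } else {
    lfnu <- NA_real_; hfnu <- NA_real_; ratio <- NA_real_
  }
  list(VLF = vlf, LF = lf, HF = hf, LFnu = lfnu, HFnu = hfnu, LF_HF = ratio)
}

#' Spectral entropy of a uniform series
#'
#' Shannon entropy of the Welch PSD normalized to unit sum over 0-2 Hz,
#' divided by `log` of the number of bins, so values lie in [0, 1]: near 0
#' for a pure tone, near 1 for white noise.
#'
#' @inheritParams band_powers
#' @param f_max Upper frequency bound, Hz.
#' @return Normalized spectral entropy, or `NA` for a zero-power series.
#' @export
spectral_entropy <- function(u, fs = NULL, nperseg = 120, f_max = 2) {
  if (inherits(u, "oxi_uniform")) {
    fs <- u$fs
    u <- u$values
  }
  if (sd(u) == 0) return(NA_real_)
  w <- welch_psd(u, fs = fs, nperseg = nperseg)
  keep <- w$freq <= f_max
  p <- w$psd[keep]
  tot <- sum(p)
  if (tot <= 0) return(NA_real_)
  p <- p[p > 0] / tot
  -sum(p * log(p)) / log(sum(keep))
}
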