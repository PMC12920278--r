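# The 37-feature catalogue computed per 60-second segment: 23 PPI features
# (13 time-domain, 3 entropy, 7 frequency-domain), 7 PWA features and 7 SpO2
# features.

#' Feature names by signal family
#'
#' @return Named list with character vectors `PPI` (23), `PWA` (7) and
#'   `SpO2` (7); 37 names in total.
#' @export
feature_families <- function() {
  list(
    PPI = c("Mean_NN", "Max_PR", "Min_PR", "SDNN", "CVNNI", "SDSD", "CVSD",
            "NN50", "pNN50", "NN20", "pNN20", "RMSSD", "Range_NN",
            "Samp_NN", "Fuzz_NN", "Disp_NN",
            "VLF", "LF", "HF", "LFnu", "HFnu", "LF_HF", "SpecEnt"),
    PWA = c("Max_PWA", "Min_PWA", "Std_PWA", "CV_PWA",
            "VLF_PWA", "LF_PWA", "HF_PWA"),
    SpO2 = c("Min_Sp", "Mean_Sp", "Std_Sp", "Var_Sp",
             "Samp_Sp", "Fuzz_Sp", "Disp_Sp")
  )
}

#' All 37 feature names
#' @return Character vector of length 37.
#' @export
feature_names <- function() unname(unlist(feature_families()))

#' The five feature combinations used for classification
#'
#' @return Named list mapping each combination (`SpO2`, `PWA+SpO2`,
#'   `PPI+SpO2`, `PWA+PPI`, `PWA+PPI+SpO2`) to its feature columns.
#' @export
feature_sets <- function() {
  fam <- feature_families()
  list(
    "SpO2" = fam$SpO2,
    "PWA+SpO2" = c(fam$PWA, fam$SpO2),
    "PPI+SpO2" = c(fam$PPI, fam$SpO2),
    "PWA+PPI" = c(fam$PWA, fam$PPI),
    "PWA+PPI+SpO2" = c(fam$PWA, fam$PPI, fam$SpO2)
  )
}

#' Time-domain pulse-rate-variability features from NN intervals
#'
#' The 13 time-domain statistics of the artifact-free (NN) pulse-to-pulse
#' intervals within a segment. `NN50`/`NN20` count successive-difference
#' magnitudes exceeding 50/20 ms; `pNN50`/`pNN20` are their percentages of
#' all difference pairs; `CVSD` is RMSSD over the mean NN.
#'
#' @param nn Valid NN intervals in seconds (>= 5 values).
#' @return Named list of 13 values (seconds, bpm, counts, percentages).
#' @export
ppi_time_features <- function(nn) {
  if (length(nn) < 5) stop("need >= 5 NN intervals", call. = FALSE)
  d <- diff(nn)
  mean_nn <- mean(nn)
  sdnn <- sd(nn)
  rmssd <- sqrt(mean(d^2))
  nn50 <- sum(abs(d) > 0.05)
  nn20 <- sum(abs(d) > 0.02)
  list(
    Mean_NN = mean_nn,
    Max_PR = 60 / min(nn),
    Min_PR = 60 / max(nn),
    SDNN = sdnn,
    CVNNI = sdnn / mean_nn,
    SDSD = sd(d),
    CVSD = rmssd / mean_nn,
    NN50 = nn50,
    pNN50 = 100 * nn50 / length(d),
    NN20 = nn20,
    pNN20 = 100 * nn20 / length(d),
    RMSSD = rmssd,
    Range_NN = max(nn) - min(nn)
  )
}

#' PWA features for one segment
#'
#' Beat-wise amplitude statistics plus spectral powers of the 4 Hz PWA series
#' (pulse amplitude variability) in the standard HRV bands.
#'
#' @param pwa_beats Valid beat-wise PWA values within the segment.
#' @param pwa_uniform 240-sample 4 Hz PWA series for the segment
#'   (`oxi_uniform` or numeric).
#' @return Named list of 7 values.
#' @export
pwa_features <- function(pwa_beats, pwa_uniform) {
  m <- mean(pwa_beats)
  s <- sd(pwa_beats)
  bp <- band_powers(pwa_uniform, fs = 4)
  list(
    Max_PWA = max(pwa_beats),
    Min_PWA = min(pwa_beats),
    Std_PWA = s,
    CV_PWA = if (m != 0) s / m else 0,
    VLF_PWA = bp$VLF,
    LF_PWA = bp$LF,
    HF_PWA = bp$HF
  )
}

# mean-decimate a series by integer factor
decimate_mean <- function(x, factor) {
  n <- floor(length(x) / factor)
  colMeans(matrix(x[seq_len(n * factor)], nrow = factor))
}

#' SpO2 features for one segment
#'
#' Statistics of the raw 16 Hz SpO2 samples plus the three entropy measures.
#' Entropies are computed on a 1 Hz mean-decimated version of the trace: at
#' 16 Hz the oximeter output is heavily oversampled relative to desaturation
#' dynamics and template matching would saturate on redundant samples.
#'
#' @param spo2 Full 60 s of SpO2 samples for the segment.
#' @param fs SpO2 sampling rate, Hz.
#' @param entropy_params List with `m`, `r`, `c_classes` for the entropies.
#' @return Named list of 7 values (% points).
#' @export
spo2_features <- function(spo2, fs = 16,
                          entropy_params = list(m = 2, r = 0.2, c_classes = 6)) {
  x1 <- if (fs > 1) decimate_mean(spo2, round(fs)) else spo2
  list(
    Min_Sp = min(spo2),
    Mean_Sp = mean(spo2),
    Std_Sp = sd(spo2),
    Var_Sp = var(spo2),
    Samp_Sp = sample_entropy(x1, m = entropy_params$m, r = entropy_params$r),
    Fuzz_Sp = fuzzy_entropy(x1, m = entropy_params$m, r = entropy_params$r),
    Disp_Sp = dispersion_entropy(x1, m = entropy_params$m,
                                 c_classes = entropy_params$c_classes)
  )
}

#' Compute the 37 features for every segment of a preprocessed recording
#'
#' Segments the recording, then for each quality-ok segment computes the PPI
#' time-domain, entropy and frequency-domain features, the PWA features, and
#' the SpO2 features. A segment is marked low-quality (features `NA`) when
#' fewer than 10 valid beats fall inside it or more than half of its beats
#' are invalid.
#'
#' @param prep An `oxi_prep` from [preprocess_recording()] (an
#'   `oxi_recording` is accepted and preprocessed on the fly).
#' @param seg_len Segment length, seconds.
#' @param min_overlap Positive-label threshold, seconds.
#' @param mode Overlap accounting mode, see [label_segment()].
#' @param entropy_params List with `m`, `r` (fraction of SD) and `c_classes`.
#' @return Tibble: `subject_id`, `start`, `label`, `arousal`, `quality`, and
#'   the 37 feature columns.
#' @export
extract_features <- function(prep, seg_len = 60, min_overlap = 10,
                             mode = c("cumulative", "single"),
                             entropy_params = list(m = 2, r = 0.2, c_classes = 6)) {
  mode <- match.arg(mode)
  if (inherits(prep, "oxi_recording")) prep <- preprocess_recording(prep)
  stopifnot(inherits(prep, "oxi_prep"))
  segs <- segment_recording(prep, seg_len = seg_len, min_overlap = min_overlap,
                            mode = mode)
  beats <- prep$beats
  fs4 <- prep$ppi_series$fs
  spo2_fs <- prep$spo2$fs
  feats <- lapply(segs$start, function(s0) {
    in_seg <- beats$peak_time >= s0 & beats$peak_time < s0 + seg_len
    vseg <- beats$valid[in_seg]
    nn <- beats$ppi[in_seg][vseg & !is.na(beats$ppi[in_seg])]
    pwa_b <- beats$pwa[in_seg][vseg]
    n_in <- sum(in_seg)
    if (n_in == 0 || sum(vseg) < 10 || mean(vseg) <= 0.5 || length(nn) < 5) {
      return(c(list(quality = "low"),
               setNames(as.list(rep(NA_real_, 37)), feature_names())))
    }
    i0 <- round(s0 * fs4)
    ppi_u <- prep$ppi_series$values[(i0 + 1):(i0 + seg_len * fs4)]
    pwa_u <- prep$pwa_series$values[(i0 + 1):(i0 + seg_len * fs4)]
    j0 <- round(s0 * spo2_fs)
    sp <- prep$spo2$values[(j0 + 1):(j0 + seg_len * spo2_fs)]

    td <- ppi_time_features(nn)
    ent <- list(
      Samp_NN = sample_entropy(ppi_u, m = entropy_params$m, r = entropy_params$r),
      Fuzz_NN = fuzzy_entropy(ppi_u, m = entropy_params$m, r = entropy_params$r),
      Disp_NN = dispersion_entropy(ppi_u, m = entropy_params$m,
                                   c_classes = entropy_params$c_classes)
    )
    bp <- band_powers(ppi_u, fs = fs4)
    fd <- list(VLF = bp$VLF, LF = bp$LF, HF = bp$HF, LFnu = bp$LFnu,
               HFnu = bp$HFnu, LF_HF = bp$LF_HF,
               SpecEnt = spectral_entropy(ppi_u, fs = fs4))
    pw <- pwa_features(pwa_b, pwa_u)
    sp_f <- spo2_features(sp, fs = spo2_fs, entropy_params = entropy_params)
    vals <- c(td, ent, fd, pw, sp_f)
    # undefined sentinels (e.g. sample entropy with no template matches)
    # demote the segment: quality-ok segments must be fully finite
    quality <- if (all(vapply(vals, is.finite, logical(1)))) "ok" else "low"
    c(list(quality = quality), vals)
  })
  dplyr::bind_cols(segs, dplyr::bind_rows(lapply(feats, tibble::as_tibble)))
}

#' Per-subject min-max normalization of feature columns
#'
#' Rescales each listed column within each subject to `(x - min) / (max -
#' min)` over that subject's segments, so amplitude-dependent features can be
#' compared across subjects without absolute thresholds. A constant column
#' maps to 0. By default both the PWA and PPI families are normalized and
#' SpO2 features are left on their physical scale; set
#' `scope = "pwa_only"` to normalize only the PWA family.
#'
#' @param features Feature tibble from [extract_features()] (multiple
#'   subjects row-bound).
#' @param scope `"pwa_ppi"` (default) or `"pwa_only"`.
#' @param columns Optional explicit column selection overriding `scope`.
#' @return The tibble with listed columns rescaled to [0, 1] per subject.
#' @export
normalize_per_subject <- function(features, scope = c("pwa_ppi", "pwa_only"),
                                  columns = NULL) {
  scope <- match.arg(scope)
  fam <- feature_families()
  if (is.null(columns)) {
    columns <- if (scope == "pwa_ppi") c(fam$PWA, fam$PPI) else fam$PWA
  }
  columns <- intersect(columns, names(features))
  n_per <- table(features$subject_id)
  if (any(n_per < 2)) {
    stop("per-subject min-max normalization undefined for subjects with a ",
         "single segment: ", paste(names(n_per)[n_per < 2], collapse = ", "),
         call. = FALSE)
  }
  minmax <- function(x) {
    lo <- min(x, na.rm = TRUE)
    hi <- max(x, na.rm = TRUE)
    if (!is.finite(lo) || !is.finite(hi) || hi == lo) return(ifelse(is.na(x), NA_real_, 0))
    (x - lo) / (hi - lo)
  }
  dplyr::ungroup(dplyr::mutate(
    dplyr::group_by(features, .data$subject_id),
    dplyr::across(dplyr::all_of(columns), minmax)
  ))
}
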