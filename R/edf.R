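# Minimal EDF (European Data Format) writer/reader for the fixture dialect
# used by this package: one channel per signal, 1-second data records,
# 16-bit samples. Only the header fields needed for round-tripping signals
# and sampling rates are interpreted.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) stop("EDF header field too long: ", x, call. = FALSE)
  formatC(x, width = -width, flag = " ")
}

edf_num <- function(x, width = 8) {
  s <- formatC(x, format = "g", digits = 7, width = -1)
  if (nchar(s) > width) s <- formatC(x, format = "g", digits = 4, width = -1)
  edf_pad(s, width)
}

#' Write signals to an EDF file
#'
#' Each signal is a `list(values, fs)` with an integer sampling rate. Data
#' records are one second long, so the written duration is truncated to whole
#' seconds. Samples are quantized to 16 bits over each channel's physical
#' range (the physical min/max actually written to the header are re-parsed so
#' quantization is consistent with what a reader will see).
#'
#' @param signals Named list of `list(values, fs)` channels.
#' @param path Output file path.
#' @param phys_dim Character vector of physical dimension labels, recycled.
#' @return `path`, invisibly.
#' @export
write_edf <- function(signals, path, phys_dim = "") {
  stopifnot(length(signals) >= 1, !is.null(names(signals)))
  fs <- vapply(signals, function(s) s$fs, numeric(1))
  if (any(fs != round(fs))) stop("write_edf requires integer sampling rates")
  dur_s <- min(vapply(signals, function(s) length(s$values) / s$fs, numeric(1)))
  n_rec <- floor(dur_s)
  if (n_rec < 1) stop("signals shorter than one 1-second data record")
  ns <- length(signals)
  phys_dim <- rep_len(phys_dim, ns)

  pmin_s <- character(ns); pmax_s <- character(ns)
  dig <- vector("list", ns)
  for (i in seq_len(ns)) {
    v <- signals[[i]]$values[seq_len(n_rec * fs[i])]
    lo <- min(v); hi <- max(v)
    if (hi <= lo) hi <- lo + 1
    pad <- (hi - lo) * 1e-4
    pmin_s[i] <- edf_num(lo - pad)
    pmax_s[i] <- edf_num(hi + pad)
    lo_r <- as.numeric(pmin_s[i]); hi_r <- as.numeric(pmax_s[i])
    dig[[i]] <- as.integer(round((v - lo_r) / (hi_r - lo_r) * 65535 - 32768))
  }

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s) writeChar(s, con, nchars = nchar(s), eos = NULL)
  wr(edf_pad("0", 8))
  wr(edf_pad("synthetic subject", 80))
  wr(edf_pad("oxipulse synthetic recording", 80))
  wr(edf_pad("01.01.00", 8))
  wr(edf_pad("00.00.00", 8))
  wr(edf_pad(256 * (ns + 1), 8))
  wr(edf_pad("", 44))
  wr(edf_pad(n_rec, 8))
  wr(edf_pad("1", 8))
  wr(edf_pad(ns, 4))
  for (i in seq_len(ns)) wr(edf_pad(names(signals)[i], 16))
  for (i in seq_len(ns)) wr(edf_pad("synthetic", 80))
  for (i in seq_len(ns)) wr(edf_pad(phys_dim[i], 8))
  for (i in seq_len(ns)) wr(pmin_s[i])
  for (i in seq_len(ns)) wr(pmax_s[i])
  for (i in seq_len(ns)) wr(edf_pad("-32768", 8))
  for (i in seq_len(ns)) wr(edf_pad("32767", 8))
  for (i in seq_len(ns)) wr(edf_pad("", 80))
  for (i in seq_len(ns)) wr(edf_pad(fs[i], 8))
  for (i in seq_len(ns)) wr(edf_pad("", 32))
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      idx <- ((r - 1) * fs[i] + 1):(r * fs[i])
      writeBin(dig[[i]][idx], con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF file written by [write_edf()]
#'
#' @param path EDF file path.
#' @return Named list of `list(values, fs)` channels.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) {
    raw <- readBin(con, "raw", n)
    trimws(rawToChar(raw))
  }
  rd(8)                                  # version
  rd(80); rd(80); rd(8); rd(8)
  rd(8)                                  # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), character(1))
  for (i in seq_len(ns)) rd(80)
  for (i in seq_len(ns)) rd(8)
  pmin <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  pmax <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  dmin <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  dmax <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  for (i in seq_len(ns)) rd(80)
  spr <- vapply(seq_len(ns), function(i) as.integer(rd(8)), integer(1))
  for (i in seq_len(ns)) rd(32)

  out <- lapply(seq_len(ns), function(i) {
    list(values = numeric(n_rec * spr[i]), fs = spr[i] / rec_dur)
  })
  names(out) <- labels
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      d <- readBin(con, "integer", spr[i], size = 2, signed = TRUE,
                   endian = "little")
      phys <- pmin[i] + (d - dmin[i]) / (dmax[i] - dmin[i]) * (pmax[i] - pmin[i])
      out[[i]]$values[((r - 1) * spr[i] + 1):(r * spr[i])] <- phys
    }
  }
  out
}

#' Write a recording to disk as EDF + CSV annotations + JSON metadata
#'
#' Produces `<subject_id>.edf` (PPG and SpO2 channels at their true sampling
#' rates), `<subject_id>_annotations.csv` (columns `kind,onset_s,duration_s`)
#' and `<subject_id>_meta.json` (subject id, recording time, reference AHI,
#' comorbidity flag) under `dir`.
#'
#' @param recording An `oxi_recording`.
#' @param dir Output directory (created if missing).
#' @param overwrite Overwrite existing files? Defaults to refusing.
#' @return Named character vector of the three file paths, invisibly.
#' @export
write_fixture <- function(recording, dir, overwrite = FALSE) {
  stopifnot(inherits(recording, "oxi_recording"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    edf = file.path(dir, paste0(recording$subject_id, ".edf")),
    annotations = file.path(dir, paste0(recording$subject_id, "_annotations.csv")),
    meta = file.path(dir, paste0(recording$subject_id, "_meta.json"))
  )
  if (!overwrite && any(file.exists(paths))) {
    stop("fixture files already exist under ", dir,
         " (use overwrite = TRUE)", call. = FALSE)
  }
  write_edf(list(PPG = recording$ppg, SpO2 = recording$spo2), paths[["edf"]],
            phys_dim = c("au", "%"))
  ann <- data.frame(kind = recording$events$kind,
                    onset_s = recording$events$onset,
                    duration_s = recording$events$duration)
  utils::write.csv(ann, paths[["annotations"]], row.names = FALSE)
  meta <- list(subject_id = recording$subject_id,
               recording_time_h = recording$recording_time_h,
               reference_ahi = recording$reference_ahi,
               comorbidity = recording$comorbidity)
  jsonlite::write_json(meta, paths[["meta"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Read a recording fixture written by [write_fixture()]
#'
#' @param dir Fixture directory.
#' @param subject_id Subject identifier used when writing.
#' @return An `oxi_recording` (without generator ground truth).
#' @export
read_fixture <- function(dir, subject_id) {
  edf <- read_edf(file.path(dir, paste0(subject_id, ".edf")))
  ann <- utils::read.csv(file.path(dir, paste0(subject_id, "_annotations.csv")))
  meta <- jsonlite::read_json(file.path(dir, paste0(subject_id, "_meta.json")),
                              simplifyVector = TRUE)
  structure(
    list(
      subject_id = meta$subject_id,
      ppg = edf$PPG,
      spo2 = edf$SpO2,
      events = tibble::tibble(kind = ann$kind, onset = ann$onset_s,
                              duration = ann$duration_s),
      recording_time_h = meta$recording_time_h,
      reference_ahi = meta$reference_ahi,
      comorbidity = isTRUE(meta$comorbidity),
      ground_truth = NULL
    ),
    class = "oxi_recording"
  )
}
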