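# Segmentation: tile each recording into non-overlapping 60-second windows
# and label them from the event annotations.

# Total intersection (seconds) of events with the half-open window
# [start, start + seg_len).
event_overlap <- function(events, start, seg_len) {
  if (nrow(events) == 0) return(numeric(0))
  lo <- pmax(events$onset, start)
  hi <- pmin(events$onset + events$duration, start + seg_len)
  pmax(0, hi - lo)
}

#' Label one 60-second window from apnea/hypopnea annotations
#'
#' A window is positive when apnea/hypopnea events occupy at least
#' `min_overlap` seconds of it. In `"cumulative"` mode (default) overlap is
#' summed across events; in `"single"` mode at least one event must on its
#' own reach `min_overlap`. Windows are half-open `[start, start + seg_len)`:
#' an event touching the right edge contributes zero overlap.
#'
#' @param events Tibble with `kind`, `onset`, `duration`; only apnea/hypopnea
#'   rows are considered.
#' @param start Window start, seconds.
#' @param seg_len Window length, seconds.
#' @param min_overlap Required occupancy, seconds.
#' @param mode `"cumulative"` or `"single"`.
#' @return `"positive"` or `"negative"`.
#' @export
label_segment <- function(events, start, seg_len = 60, min_overlap = 10,
                          mode = c("cumulative", "single")) {
  mode <- match.arg(mode)
  resp <- events[events$kind %in% c("obstructive_apnea", "hypopnea"), ,
                 drop = FALSE]
  ov <- event_overlap(resp, start, seg_len)
  hit <- if (mode == "cumulative") sum(ov) >= min_overlap
         else any(ov >= min_overlap)
  if (isTRUE(hit)) "positive" else "negative"
}

#' Tag a window as arousal-associated
#'
#' `TRUE` when at least one arousal annotation intersects the half-open
#' window by strictly more than zero seconds.
#'
#' @inheritParams label_segment
#' @return Logical.
#' @export
tag_arousal <- function(events, start, seg_len = 60) {
  ar <- events[events$kind == "arousal", , drop = FALSE]
  any(event_overlap(ar, start, seg_len) > 0)
}

#' Cut a recording into labeled non-overlapping 60-second segments
#'
#' Produces `floor(duration / seg_len)` segments; a trailing partial window is
#' discarded. Labels come only from apnea/hypopnea annotations and the
#' arousal flag only from arousal annotations.
#'
#' @param recording An `oxi_recording` or `oxi_prep` object (anything with
#'   `events` and `recording_time_h`).
#' @param seg_len Segment length, seconds.
#' @param min_overlap Positive-label occupancy threshold, seconds.
#' @param mode Overlap accounting mode, see [label_segment()].
#' @return Tibble with `subject_id`, `start`, `length`, `label`, `arousal`.
#' @export
segment_recording <- function(recording, seg_len = 60, min_overlap = 10,
                              mode = c("cumulative", "single")) {
  mode <- match.arg(mode)
  dur_s <- recording$recording_time_h * 3600
  if (dur_s < seg_len) {
    stop("recording shorter than one segment (", dur_s, " s < ", seg_len,
         " s)", call. = FALSE)
  }
  n_seg <- floor(dur_s / seg_len)
  starts <- (seq_len(n_seg) - 1) * seg_len
  tibble::tibble(
    subject_id = recording$subject_id,
    start = starts,
    length = seg_len,
    label = vapply(starts, function(s)
      label_segment(recording$events, s, seg_len, min_overlap, mode),
      character(1)),
    arousal = vapply(starts, function(s)
      tag_arousal(recording$events, s, seg_len), logical(1))
  )
}
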