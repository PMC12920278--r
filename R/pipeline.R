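# End-to-end pipeline: synthesize (or load) a cohort, preprocess, segment,
# extract and normalize features, run nested CV, and evaluate.

#' Build a pipeline run configuration
#'
#' All stage parameters in one serializable list. `synth` controls the
#' synthetic cohort (set `n_subjects` etc.); alternatively supply recordings
#' directly to [run_pipeline()].
#'
#' @param n_subjects Cohort size.
#' @param duration_h Recording length per subject, hours.
#' @param severity_mix Fractions over the four AHI severity bins.
#' @param sets Feature-set name(s) for modeling, or `"all"`.
#' @param k Outer cross-validation folds.
#' @param seed Global seed; stage seeds are derived from it.
#' @param seg_len Segment length, seconds.
#' @param min_overlap Positive-label occupancy threshold, seconds.
#' @param overlap_mode `"cumulative"` or `"single"`.
#' @param normalization `"pwa_ppi"` or `"pwa_only"`.
#' @param ahi_threshold Screening threshold, events/h.
#' @param synth Extra arguments for [synth_config()].
#' @return A list of class `oxi_run_config`.
#' @export
run_config <- function(n_subjects = 12, duration_h = 2,
                       severity_mix = c(0.122, 0.244, 0.356, 0.278),
                       sets = "PWA+PPI+SpO2", k = 5, seed = 1L,
                       seg_len = 60, min_overlap = 10,
                       overlap_mode = "cumulative",
                       normalization = "pwa_ppi",
                       ahi_threshold = 15,
                       synth = list()) {
  structure(
    list(n_subjects = n_subjects, duration_h = duration_h,
         severity_mix = severity_mix, sets = sets, k = k,
         seed = as.integer(seed), seg_len = seg_len,
         min_overlap = min_overlap, overlap_mode = overlap_mode,
         normalization = normalization, ahi_threshold = ahi_threshold,
         synth = synth),
    class = "oxi_run_config"
  )
}

#' Read / write a run configuration as YAML
#'
#' @param path YAML file path.
#' @return [load_run_config()] returns an `oxi_run_config`.
#' @export
load_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(run_config, cfg)
}

#' @param config An `oxi_run_config`.
#' @rdname load_run_config
#' @export
save_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Extract and normalize features for a list of recordings
#'
#' Convenience wrapper: preprocess each recording, extract the 37 features
#' per segment, row-bind across subjects, and apply per-subject min-max
#' normalization.
#'
#' @param recordings List of `oxi_recording` objects.
#' @param seg_len,min_overlap,mode Segmentation parameters.
#' @param normalization Normalization scope, see [normalize_per_subject()].
#' @return Normalized feature tibble.
#' @export
cohort_features <- function(recordings, seg_len = 60, min_overlap = 10,
                            mode = "cumulative", normalization = "pwa_ppi") {
  feats <- dplyr::bind_rows(lapply(recordings, function(rec) {
    extract_features(preprocess_recording(rec), seg_len = seg_len,
                     min_overlap = min_overlap, mode = mode)
  }))
  normalize_per_subject(feats, scope = normalization)
}

subject_info_table <- function(recordings) {
  dplyr::bind_rows(lapply(recordings, function(rec) {
    tibble::tibble(subject_id = rec$subject_id,
                   recording_time_h = rec$recording_time_h,
                   ref_ahi = rec$reference_ahi,
                   comorbidity = rec$comorbidity)
  }))
}

#' Run the full screening pipeline
#'
#' Executes synthesis (unless `recordings` is given), preprocessing,
#' segmentation, feature extraction, nested cross-validation and evaluation,
#' logging row counts per stage. With an output directory the resolved
#' config, per-fold metrics, screening summary, AHI table and importances
#' are written as YAML/CSV/JSON.
#'
#' @param config An `oxi_run_config`.
#' @param recordings Optional list of `oxi_recording` objects to use instead
#'   of synthesizing a cohort.
#' @param out_dir Optional output directory.
#' @param quiet Suppress progress messages.
#' @return List of class `oxi_report`: `cv` (`oxi_cv`), `fold_metrics`,
#'   `summary`, `arousal_detection`, `screening` (per feature set),
#'   `importance`, `subjects`, `config`.
#' @export
run_pipeline <- function(config = run_config(), recordings = NULL,
                         out_dir = NULL, quiet = FALSE) {
  stopifnot(inherits(config, "oxi_run_config"))
  say <- function(...) if (!quiet) message(...)

  if (is.null(recordings)) {
    say("synth: generating ", config$n_subjects, " subjects x ",
        config$duration_h, " h")
    base_cfg <- do.call(synth_config, config$synth)
    recordings <- generate_cohort(config$n_subjects, config$severity_mix,
                                  duration_h = config$duration_h,
                                  seed = derive_seed(config$seed, "synth"),
                                  base_config = base_cfg)
  }
  subjects <- subject_info_table(recordings)

  say("features: preprocessing and extracting 37 features per segment")
  features <- cohort_features(recordings, seg_len = config$seg_len,
                              min_overlap = config$min_overlap,
                              mode = config$overlap_mode,
                              normalization = config$normalization)
  say("features: ", nrow(features), " segments (",
      sum(features$quality != "ok"), " low-quality excluded from modeling)")

  say("modeling: nested ", config$k, "-fold CV on ",
      paste(config$sets, collapse = ", "))
  cv <- run_nested_cv(features, sets = config$sets, k = config$k,
                      seed = derive_seed(config$seed, "model"))

  fold_metrics <- tidy(cv)
  summary_tbl <- glance(cv)

  sets_used <- unique(cv$predictions$feature_set)
  arousal <- lapply(sets_used, function(s) {
    p <- cv$predictions[cv$predictions$feature_set == s, ]
    dplyr::bind_cols(tibble::tibble(feature_set = s),
                     arousal_stratified_detection(p$pred, p$label, p$arousal))
  })
  arousal <- dplyr::bind_rows(arousal)

  screening <- lapply(sets_used, function(s) {
    ahi <- ahi_from_cv(cv, subjects, set = s)
    screen_subjects(ahi, threshold = config$ahi_threshold,
                    stratum = if ("comorbidity" %in% names(ahi)) "comorbidity")
  })
  names(screening) <- sets_used

  importance <- feature_importance(cv, set = sets_used[[length(sets_used)]])

  report <- structure(
    list(cv = cv, fold_metrics = fold_metrics, summary = summary_tbl,
         arousal_detection = arousal, screening = screening,
         importance = importance, subjects = subjects, config = config),
    class = "oxi_report"
  )

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    save_run_config(config, file.path(out_dir, "config.yaml"))
    utils::write.csv(fold_metrics, file.path(out_dir, "fold_metrics.csv"),
                     row.names = FALSE)
    utils::write.csv(arousal, file.path(out_dir, "arousal_detection.csv"),
                     row.names = FALSE)
    utils::write.csv(importance, file.path(out_dir, "importance.csv"),
                     row.names = FALSE)
    screen_json <- lapply(screening, function(s) {
      list(summary = s$summary, subjects = s$subjects)
    })
    jsonlite::write_json(
      list(summary = summary_tbl, screening = screen_json),
      file.path(out_dir, "metrics.json"), digits = 10, dataframe = "rows")
  }
  report
}

#' @export
print.oxi_report <- function(x, ...) {
  cat("<oxi_report>\n")
  print(x$summary)
  for (s in names(x$screening)) {
    cat("screening [", s, "]: ", sep = "")
    print(x$screening[[s]])
  }
  invisible(x)
}
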