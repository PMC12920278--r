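# Evaluation surfaces: per-segment classification metrics, arousal-stratified
# detection, per-subject AHI estimation, AHI >= 15 screening and feature
# importance.

#' Per-segment classification metrics
#'
#' Accuracy, sensitivity, specificity and precision in percent, plus the AUC
#' of the continuous decision score. Returns `NA` for metrics whose
#' denominator is empty (e.g. AUC in a single-class fold).
#'
#' @param pred Predicted labels (`"positive"`/`"negative"`, factor or
#'   logical).
#' @param label True labels.
#' @param score Continuous decision scores (larger = more positive).
#' @return One-row tibble: `n`, `accuracy`, `sensitivity`, `specificity`,
#'   `precision` (percent), `auc`.
#' @export
segment_metrics <- function(pred, label, score = NULL) {
  p <- truth_to_logical(pred)
  y <- truth_to_logical(label)
  tp <- sum(p & y); fn <- sum(!p & y)
  tn <- sum(!p & !y); fp <- sum(p & !y)
  pct <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  tibble::tibble(
    n = length(y),
    accuracy = pct(tp + tn, length(y)),
    sensitivity = pct(tp, tp + fn),
    specificity = pct(tn, tn + fp),
    precision = pct(tp, tp + fp),
    auc = if (is.null(score)) NA_real_ else auc_score(score, y)
  )
}

#' Detection rate of positive segments with and without arousals
#'
#' Recall (percent of true positive segments predicted positive) computed
#' separately within the arousal-associated and non-arousal strata.
#'
#' @param pred Predicted labels.
#' @param label True labels.
#' @param arousal Logical arousal flags.
#' @return Tibble with rows `with_arousal` and `no_arousal`: `n_positive`,
#'   `detected`, `recall_pct` (`NA` for an empty stratum).
#' @export
arousal_stratified_detection <- function(pred, label, arousal) {
  p <- truth_to_logical(pred)
  y <- truth_to_logical(label)
  one <- function(mask) {
    n <- sum(y & mask)
    det <- sum(y & mask & p)
    tibble::tibble(n_positive = n, detected = det,
                   recall_pct = if (n > 0) 100 * det / n else NA_real_)
  }
  dplyr::bind_cols(
    tibble::tibble(stratum = c("with_arousal", "no_arousal")),
    dplyr::bind_rows(one(arousal), one(!arousal))
  )
}

#' Estimate the apnea-hypopnea index from segment predictions
#'
#' AHI = number of positive segments divided by the recording time in hours.
#' Each 60-second positive segment therefore counts as one event; the
#' denominator is recording time, not total sleep time.
#'
#' @param pred Predicted segment labels for one subject.
#' @param recording_time_h Recording duration, hours.
#' @return Estimated AHI, events per hour.
#' @export
estimate_ahi <- function(pred, recording_time_h) {
  assert_positive(recording_time_h, "recording_time_h")
  sum(truth_to_logical(pred)) / recording_time_h
}

#' OSA severity class from an AHI value
#'
#' No OSA for AHI < 5, mild for 5 <= AHI < 15, moderate for 15 <= AHI <= 30,
#' severe for AHI > 30.
#'
#' @param ahi Numeric AHI values (>= 0).
#' @return Factor with levels `none`, `mild`, `moderate`, `severe`.
#' @export
severity_class <- function(ahi) {
  if (any(is.na(ahi)) || any(ahi < 0)) {
    stop("AHI must be non-negative", call. = FALSE)
  }
  out <- ifelse(ahi < 5, "none",
         ifelse(ahi < 15, "mild",
         ifelse(ahi <= 30, "moderate", "severe")))
  factor(out, levels = c("none", "mild", "moderate", "severe"))
}

screening_summary <- function(subjects, threshold) {
  est_pos <- subjects$est_ahi >= threshold
  ref_pos <- subjects$ref_ahi >= threshold
  tp <- sum(est_pos & ref_pos); fn <- sum(!est_pos & ref_pos)
  tn <- sum(!est_pos & !ref_pos); fp <- sum(est_pos & !ref_pos)
  tibble::tibble(
    n = nrow(subjects),
    n_ref_positive = tp + fn,
    sensitivity = if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_,
    pearson_r = if (nrow(subjects) > 2) cor(subjects$est_ahi, subjects$ref_ahi)
                else NA_real_,
    tp = tp, fn = fn, tn = tn, fp = fp
  )
}

#' Screen subjects for moderate-to-severe OSA
#'
#' A subject screens positive when the estimated AHI is at or above
#' `threshold` (default 15). Reports per-subject sensitivity and specificity
#' against the reference AHI, the 2x2 confusion matrix, and the Pearson
#' correlation between estimated and reference AHI; optionally recomputed
#' within strata (e.g. a comorbidity subgroup).
#'
#' @param subjects Tibble with `subject_id`, `est_ahi`, `ref_ahi` and
#'   optionally a stratum column.
#' @param threshold Screening AHI threshold, events/h.
#' @param stratum Optional name of a column in `subjects` defining strata.
#' @return Object of class `oxi_screening`: `subjects` (with `decision` and
#'   `ref_positive`), `summary` (overall plus per-stratum rows), `confusion`
#'   (2x2 matrix), `threshold`.
#' @export
screen_subjects <- function(subjects, threshold = 15, stratum = NULL) {
  stopifnot(all(c("subject_id", "est_ahi", "ref_ahi") %in% names(subjects)))
  subjects <- dplyr::mutate(subjects,
                            decision = .data$est_ahi >= threshold,
                            ref_positive = .data$ref_ahi >= threshold)
  summ <- dplyr::bind_cols(tibble::tibble(stratum = "all"),
                           screening_summary(subjects, threshold))
  if (!is.null(stratum)) {
    for (lev in unique(subjects[[stratum]])) {
      sub <- subjects[subjects[[stratum]] == lev, , drop = FALSE]
      if (nrow(sub) == 0) {
        warning("empty stratum ", lev, " omitted")
        next
      }
      summ <- dplyr::bind_rows(
        summ,
        dplyr::bind_cols(tibble::tibble(stratum = paste0(stratum, "=", lev)),
                         screening_summary(sub, threshold)))
    }
  }
  confusion <- matrix(
    c(summ$tp[1], summ$fn[1], summ$fp[1], summ$tn[1]), nrow = 2,
    dimnames = list(estimated = c("AHI>=15", "AHI<15"),
                    reference = c("AHI>=15", "AHI<15")))
  structure(list(subjects = subjects, summary = summ, confusion = confusion,
                 threshold = threshold),
            class = "oxi_screening")
}

#' @export
print.oxi_screening <- function(x, ...) {
  s <- x$summary[1, ]
  cat(sprintf(
    "<oxi_screening> %d subjects, threshold AHI >= %g: sensitivity %.1f%%, specificity %.1f%%, r = %.2f\n",
    s$n, x$threshold, s$sensitivity, s$specificity, s$pearson_r))
  invisible(x)
}

#' Mean random-forest feature importance across folds
#'
#' Per-fold normalized impurity importances averaged across folds; a feature
#' not selected in a fold contributes zero for that fold.
#'
#' @param cv An `oxi_cv` object (or its `importances` tibble).
#' @param set Feature-set name to report (default: first available).
#' @return Tibble `feature`, `mean_importance`, `n_folds_selected`, sorted
#'   decreasing; class `oxi_importance`.
#' @export
feature_importance <- function(cv, set = NULL) {
  imp <- if (inherits(cv, "oxi_cv")) cv$importances else cv
  if (is.null(set)) set <- imp$feature_set[1]
  imp <- imp[imp$feature_set == set, , drop = FALSE]
  n_folds <- length(unique(imp$fold))
  out <- dplyr::arrange(
    dplyr::summarise(
      dplyr::group_by(imp, .data$feature),
      mean_importance = sum(.data$importance) / n_folds,
      n_folds_selected = dplyr::n(), .groups = "drop"),
    dplyr::desc(.data$mean_importance))
  class(out) <- c("oxi_importance", class(out))
  attr(out, "feature_set") <- set
  out
}

#' Per-subject AHI estimates from nested-CV predictions
#'
#' Pools each subject's held-out segment predictions (every subject appears
#' in exactly one test fold) and converts the positive-segment count into an
#' AHI estimate.
#'
#' @param cv An `oxi_cv` object.
#' @param subject_info Tibble with `subject_id`, `recording_time_h`,
#'   `ref_ahi` and optionally `comorbidity`.
#' @param set Feature-set name (default: first available).
#' @return Tibble with one row per subject: `subject_id`, `est_ahi`,
#'   `ref_ahi`, plus any extra columns of `subject_info`.
#' @export
ahi_from_cv <- function(cv, subject_info, set = NULL) {
  stopifnot(inherits(cv, "oxi_cv"))
  preds <- cv$predictions
  if (is.null(set)) set <- preds$feature_set[1]
  preds <- preds[preds$feature_set == set, , drop = FALSE]
  est <- dplyr::summarise(
    dplyr::group_by(preds, .data$subject_id),
    n_positive = sum(.data$pred == "positive"), .groups = "drop")
  out <- dplyr::left_join(est, subject_info, by = "subject_id")
  out$est_ahi <- out$n_positive / out$recording_time_h
  out
}

#' Compare per-fold metrics across feature sets
#'
#' Repeated-measures ANOVA over folds followed by Bonferroni-corrected paired
#' t-tests of each feature set against a reference set, applied to one
#' per-fold metric (e.g. sensitivity or AUC).
#'
#' @param fold_metrics Tibble with `feature_set`, `fold` and the metric
#'   column.
#' @param metric Name of the metric column.
#' @param reference Reference feature-set name.
#' @return List with `anova_p` and a tibble `pairwise` of Bonferroni-adjusted
#'   p-values against the reference.
#' @export
compare_feature_sets <- function(fold_metrics, metric = "auc",
                                 reference = "SpO2") {
  df <- data.frame(set = factor(fold_metrics$feature_set),
                   fold = factor(fold_metrics$fold),
                   y = fold_metrics[[metric]])
  fit <- aov(y ~ set + Error(fold), data = df)
  tab <- summary(fit)[["Error: Within"]][[1]]
  anova_p <- tab[["Pr(>F)"]][1]
  others <- setdiff(levels(df$set), reference)
  pw <- lapply(others, function(s) {
    a <- df$y[df$set == s][order(df$fold[df$set == s])]
    b <- df$y[df$set == reference][order(df$fold[df$set == reference])]
    tibble::tibble(feature_set = s, p_value = t.test(a, b, paired = TRUE)$p.value)
  })
  pw <- dplyr::bind_rows(pw)
  pw$p_adj <- p.adjust(pw$p_value, method = "bonferroni")
  list(anova_p = anova_p, pairwise = pw, reference = reference,
       metric = metric)
}
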