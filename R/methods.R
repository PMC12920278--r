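# broom-style accessors for fitted objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Per-fold segment metrics from a nested-CV result
#'
#' @param x An `oxi_cv` object.
#' @param ... Unused.
#' @return Tibble: one row per feature set and outer fold with `n`,
#'   `accuracy`, `sensitivity`, `specificity`, `precision` (percent) and
#'   `auc`.
#' @method tidy oxi_cv
#' @export
tidy.oxi_cv <- function(x, ...) {
  dplyr::ungroup(dplyr::reframe(
    dplyr::group_by(x$predictions, .data$feature_set, .data$fold),
    segment_metrics(.data$pred, .data$label, .data$score)))
}

#' One-row-per-feature-set summary (mean +/- SD across folds)
#'
#' @param x An `oxi_cv` object.
#' @param ... Unused.
#' @return Tibble with mean and SD of each per-segment metric across outer
#'   folds plus the mean number of selected features.
#' @method glance oxi_cv
#' @export
glance.oxi_cv <- function(x, ...) {
  per_fold <- tidy(x)
  sel <- dplyr::summarise(dplyr::group_by(x$folds, .data$feature_set),
                          n_features_mean = mean(.data$n_selected),
                          n_features_sd = sd(.data$n_selected),
                          .groups = "drop")
  agg <- dplyr::summarise(
    dplyr::group_by(per_fold, .data$feature_set),
    dplyr::across(c("accuracy", "sensitivity", "specificity", "precision", "auc"),
                  list(mean = ~mean(.x, na.rm = TRUE),
                       sd = ~sd(.x, na.rm = TRUE))),
    .groups = "drop")
  dplyr::left_join(sel, agg, by = "feature_set")
}

#' Per-subject screening table
#'
#' @param x An `oxi_screening` object.
#' @param ... Unused.
#' @return The per-subject tibble with decisions.
#' @method tidy oxi_screening
#' @export
tidy.oxi_screening <- function(x, ...) x$subjects

#' Screening summary row(s)
#'
#' @param x An `oxi_screening` object.
#' @param ... Unused.
#' @return The summary tibble (overall and any strata).
#' @method glance oxi_screening
#' @export
glance.oxi_screening <- function(x, ...) x$summary
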