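# ggplot2 displays for the main result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_abline geom_col
#'   geom_hline labs coord_flip theme_minimal annotate geom_boxplot geom_tile
#'   geom_text scale_fill_gradient
#' @export
ggplot2::autoplot

#' Scatter of estimated versus reference AHI
#'
#' One point per subject, identity line, and the Pearson correlation in the
#' caption. Points above/below the screening threshold lines correspond to
#' the confusion-matrix cells.
#'
#' @param object An `oxi_screening` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot oxi_screening
#' @export
autoplot.oxi_screening <- function(object, ...) {
  s <- object$subjects
  r <- object$summary$pearson_r[1]
  ggplot(s, aes(x = .data$ref_ahi, y = .data$est_ahi)) +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed", colour = "grey50") +
    geom_hline(yintercept = object$threshold, linetype = "dotted") +
    geom_point(aes(colour = .data$ref_positive), size = 2) +
    labs(x = "Reference AHI (events/h)", y = "Estimated AHI (events/h)",
         colour = paste0("Reference AHI ≥ ", object$threshold),
         caption = sprintf("Pearson r = %.2f", r)) +
    theme_minimal()
}

#' Screening confusion matrix as a tile plot
#'
#' @param screening An `oxi_screening` object.
#' @return A ggplot.
#' @export
plot_confusion <- function(screening) {
  cm <- screening$confusion
  df <- tibble::tibble(
    estimated = rep(rownames(cm), 2),
    reference = rep(colnames(cm), each = 2),
    count = as.vector(cm)
  )
  ggplot(df, aes(x = .data$reference, y = .data$estimated, fill = .data$count)) +
    geom_tile() +
    geom_text(aes(label = .data$count), colour = "white", size = 6) +
    scale_fill_gradient(low = "grey60", high = "steelblue4") +
    labs(x = "Reference", y = "Estimated") +
    theme_minimal()
}

#' Top-k mean feature importances
#'
#' @param object An `oxi_importance` tibble from [feature_importance()].
#' @param top_k Number of features to show.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot oxi_importance
#' @export
autoplot.oxi_importance <- function(object, top_k = 20, ...) {
  df <- head(object, top_k)
  df$feature <- factor(df$feature, levels = rev(df$feature))
  ggplot(df, aes(x = .data$feature, y = .data$mean_importance)) +
    geom_col(fill = "steelblue4") +
    coord_flip() +
    labs(x = NULL, y = "Mean importance across folds") +
    theme_minimal()
}

#' Per-fold metric distributions across feature sets
#'
#' @param object An `oxi_cv` object.
#' @param metric Metric column of [tidy.oxi_cv()] to display.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot oxi_cv
#' @export
autoplot.oxi_cv <- function(object, metric = "auc", ...) {
  df <- tidy(object)
  ggplot(df, aes(x = .data$feature_set, y = .data[[metric]])) +
    geom_boxplot(outlier.shape = NA, fill = "grey90") +
    geom_point(aes(colour = factor(.data$fold)), size = 2) +
    labs(x = NULL, y = metric, colour = "fold") +
    theme_minimal()
}
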