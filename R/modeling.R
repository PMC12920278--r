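# Per-segment classification under subject-grouped nested cross-validation:
# random-forest RFECV feature selection, random undersampling, and a small
# SVM hyperparameter search, all confined to training-fold rows.

#' Assign subjects to cross-validation folds
#'
#' Subject-level partition into `k` folds whose sizes differ by at most one
#' subject; every segment inherits its subject's fold, so held-out subjects
#' never contribute training rows.
#'
#' @param subject_ids Character vector (one entry per segment, or the unique
#'   subjects).
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Tibble `subject_id`, `fold`.
#' @export
make_grouped_folds <- function(subject_ids, k = 5, seed = 1L) {
  subjects <- sort(unique(subject_ids))
  if (k > length(subjects)) {
    stop("k = ", k, " folds but only ", length(subjects), " subjects",
         call. = FALSE)
  }
  set.seed(derive_seed(seed, "folds"))
  shuffled <- sample(subjects)
  tibble::tibble(subject_id = shuffled,
                 fold = rep_len(seq_len(k), length(subjects)))
}

#' Random undersampling to exact class balance
#'
#' Randomly subsamples the majority class without replacement down to the
#' minority-class count.
#'
#' @param rows Data frame with a `label` column (`"positive"`/`"negative"`).
#' @param seed Integer seed.
#' @return The balanced rows (original row order within class preserved).
#' @export
undersample <- function(rows, seed = 1L) {
  pos <- which(truth_to_logical(rows$label))
  neg <- which(!truth_to_logical(rows$label))
  if (length(pos) == 0L || length(neg) == 0L) {
    stop("undersampling requires both classes present", call. = FALSE)
  }
  set.seed(derive_seed(seed, "undersample"))
  if (length(pos) > length(neg)) {
    pos <- sort(sample(pos, length(neg)))
  } else if (length(neg) > length(pos)) {
    neg <- sort(sample(neg, length(pos)))
  }
  rows[sort(c(pos, neg)), , drop = FALSE]
}

fit_rf <- function(x, y, seed, num_trees = 100) {
  df <- data.frame(x, check.names = FALSE)
  df$.label <- label_factor(y)
  ranger::ranger(
    dependent.variable.name = ".label", data = df,
    num.trees = num_trees, probability = TRUE,
    importance = "impurity", seed = seed, num.threads = 1
  )
}

rf_scores <- function(fit, x) {
  p <- predict(fit, data.frame(x, check.names = FALSE),
               num.threads = 1)$predictions
  p[, "positive"]
}

# One recursive-elimination pass: fit, record validation AUC (if given),
# drop the least important feature, repeat down to one feature.
rfe_path <- function(train_x, train_y, val_x = NULL, val_y = NULL, seed,
                     num_trees = 100) {
  cols <- colnames(train_x)
  sizes <- integer(0)
  aucs <- numeric(0)
  order_removed <- character(0)
  current <- cols
  step <- 0L
  while (length(current) >= 1L) {
    step <- step + 1L
    fit <- fit_rf(train_x[, current, drop = FALSE], train_y,
                  seed = seed + step)
    sizes <- c(sizes, length(current))
    if (!is.null(val_x)) {
      sc <- rf_scores(fit, val_x[, current, drop = FALSE])
      aucs <- c(aucs, auc_score(sc, val_y))
    }
    if (length(current) == 1L) break
    imp <- fit$variable.importance[current]
    drop <- names(which.min(imp))
    order_removed <- c(order_removed, drop)
    current <- setdiff(current, drop)
  }
  list(sizes = sizes, aucs = aucs, order_removed = order_removed,
       last = current)
}

#' Recursive feature elimination with inner cross-validation (RFECV)
#'
#' Features are recursively eliminated one at a time, ranked by random-forest
#' impurity importance. For each inner (subject-grouped) split the validation
#' AUC is recorded at every subset size; the chosen size is the smallest
#' whose mean AUC is within one standard error of the best. A final
#' elimination pass on all training rows returns that many features.
#'
#' @param train_rows Training-fold rows (feature columns + `label` +
#'   `subject_id`).
#' @param columns Candidate feature columns.
#' @param k_inner Inner folds.
#' @param seed Integer seed.
#' @param num_trees Trees per random forest.
#' @return Character vector of selected columns; attribute `cv_scores` holds
#'   the size-by-split AUC table.
#' @export
select_features_rfecv <- function(train_rows, columns, k_inner = 5, seed = 1L,
                                  num_trees = 100) {
  if (length(columns) < 1) stop("no candidate columns", call. = FALSE)
  x <- as.matrix(train_rows[, columns, drop = FALSE])
  constant <- apply(x, 2, function(v) length(unique(v[!is.na(v)])) <= 1L)
  if (any(constant)) {
    warning("dropping constant columns before RFECV: ",
            paste(columns[constant], collapse = ", "))
    columns <- columns[!constant]
    x <- x[, columns, drop = FALSE]
  }
  if (length(columns) == 1L) return(columns)
  y <- train_rows$label
  folds <- make_grouped_folds(train_rows$subject_id,
                              k = min(k_inner, length(unique(train_rows$subject_id))),
                              seed = derive_seed(seed, "rfecv"))
  fmap <- setNames(folds$fold, folds$subject_id)
  seg_fold <- fmap[train_rows$subject_id]

  p <- length(columns)
  auc_mat <- matrix(NA_real_, nrow = p, ncol = max(seg_fold))
  for (f in sort(unique(seg_fold))) {
    tr <- seg_fold != f
    if (length(unique(truth_to_logical(y[tr]))) < 2) next
    path <- rfe_path(x[tr, , drop = FALSE], y[tr],
                     x[!tr, , drop = FALSE], y[!tr],
                     seed = derive_seed(seed, "rfe_inner", f),
                     num_trees = num_trees)
    auc_mat[match(path$sizes, p:1), f] <- path$aucs
  }
  mean_auc <- rowMeans(auc_mat, na.rm = TRUE)
  sizes <- p:1
  best <- which.max(mean_auc)
  se_best <- sd(auc_mat[best, ], na.rm = TRUE) / sqrt(sum(!is.na(auc_mat[best, ])))
  if (!is.finite(se_best)) se_best <- 0
  ok_sizes <- sizes[mean_auc >= mean_auc[best] - se_best]
  chosen <- min(ok_sizes)

  final <- rfe_path(x, y, seed = derive_seed(seed, "rfe_final"),
                    num_trees = num_trees)
  keep_order <- c(final$order_removed, final$last)   # elimination order
  selected <- keep_order[(p - chosen + 1):p]
  selected <- columns[columns %in% selected]          # restore column order
  attr(selected, "cv_scores") <- tibble::tibble(size = sizes, mean_auc = mean_auc)
  selected
}

standardize_fit <- function(x) {
  mu <- colMeans(x)
  sdv <- apply(x, 2, sd)
  sdv[!is.finite(sdv) | sdv == 0] <- 1
  list(center = mu, scale = sdv)
}

standardize_apply <- function(x, sc) {
  sweep(sweep(x, 2, sc$center), 2, sc$scale, "/")
}

#' Tune and train the segment SVM
#'
#' Exhaustive search over the four-point grid (cost in {0.1, 1}, kernel in
#' {RBF, polynomial degree 3}) maximizing inner subject-grouped 5-fold CV
#' AUC, then a final fit on all (balanced) training rows. Features are
#' z-scored with training-fitted center/scale. The classifier exposes a
#' continuous decision score oriented so larger means more positive, and a
#' binary prediction at score 0.
#'
#' @param train_rows Balanced training rows (`label`, `subject_id`, feature
#'   columns).
#' @param columns Feature columns to use.
#' @param cost_grid,kernels Hyperparameter grid.
#' @param k_inner Inner folds.
#' @param seed Integer seed.
#' @return Object of class `oxi_svm`.
#' @export
tune_and_train <- function(train_rows, columns, cost_grid = c(0.1, 1),
                           kernels = c("radial", "polynomial"), k_inner = 5,
                           seed = 1L) {
  x <- as.matrix(train_rows[, columns, drop = FALSE])
  y <- label_factor(train_rows$label)
  sc <- standardize_fit(x)
  xs <- standardize_apply(x, sc)

  grid <- expand.grid(cost = cost_grid, kernel = kernels,
                      stringsAsFactors = FALSE)
  folds <- make_grouped_folds(train_rows$subject_id,
                              k = min(k_inner, length(unique(train_rows$subject_id))),
                              seed = derive_seed(seed, "svm_tune"))
  fmap <- setNames(folds$fold, folds$subject_id)
  seg_fold <- fmap[train_rows$subject_id]

  cv_auc <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    aucs <- c()
    for (f in sort(unique(seg_fold))) {
      tr <- seg_fold != f
      if (length(unique(y[tr])) < 2 || length(unique(y[!tr])) < 2) next
      fit <- svm_fit(xs[tr, , drop = FALSE], y[tr], grid$cost[g], grid$kernel[g])
      sc_val <- svm_score(fit, xs[!tr, , drop = FALSE])
      aucs <- c(aucs, auc_score(sc_val, y[!tr]))
    }
    cv_auc[g] <- mean(aucs, na.rm = TRUE)
  }
  best <- which.max(cv_auc)
  fit <- svm_fit(xs, y, grid$cost[best], grid$kernel[best])
  structure(
    list(model = fit$model, flip = fit$flip, columns = columns,
         center = sc$center, scale = sc$scale,
         cost = grid$cost[best], kernel = grid$kernel[best],
         cv_auc = cv_auc[best], grid = cbind(grid, cv_auc = cv_auc)),
    class = "oxi_svm"
  )
}

svm_fit <- function(xs, y, cost, kernel) {
  model <- e1071::svm(xs, y, kernel = kernel, cost = cost, degree = 3,
                      scale = FALSE)
  dv <- attr(predict(model, xs, decision.values = TRUE), "decision.values")[, 1]
  a <- auc_score(dv, y)
  flip <- is.finite(a) && a < 0.5
  list(model = model, flip = flip)
}

svm_score <- function(fit, xs) {
  dv <- attr(predict(fit$model, xs, decision.values = TRUE),
             "decision.values")[, 1]
  if (fit$flip) -dv else dv
}

#' Predict segment scores and labels with a trained SVM
#'
#' @param object An `oxi_svm`.
#' @param newdata Data frame containing the model's feature columns.
#' @param ... Unused.
#' @return Tibble with `score` (continuous, larger = more apneic) and `pred`
#'   (`"positive"` iff score > 0).
#' @export
predict.oxi_svm <- function(object, newdata, ...) {
  x <- as.matrix(newdata[, object$columns, drop = FALSE])
  xs <- standardize_apply(x, list(center = object$center, scale = object$scale))
  score <- svm_score(object, xs)
  tibble::tibble(score = score,
                 pred = ifelse(score > 0, "positive", "negative"))
}

#' Subject-grouped nested cross-validation over feature combinations
#'
#' For each feature combination and each outer fold: RFECV feature selection
#' on the training subjects, random undersampling to class balance, SVM
#' hyperparameter tuning and final fit, then prediction of every quality-ok
#' held-out segment. A per-fold random forest (on the selected features,
#' balanced rows) is retained for feature-importance reporting.
#'
#' @param features Normalized feature tibble (multiple subjects).
#' @param sets Character vector of feature-set names (see [feature_sets()]),
#'   or `"all"`.
#' @param k Outer folds.
#' @param seed Integer seed controlling folds, undersampling, RFECV and
#'   tuning.
#' @param num_trees Trees per random forest.
#' @param rfecv Set to `FALSE` to skip feature selection (all columns used).
#' @return Object of class `oxi_cv`: `predictions` (per-segment tibble),
#'   `folds` (per-fold metadata with selected features and hyperparameters),
#'   `importances`, `subjects` (per-subject metadata), `n_low_quality`.
#' @export
run_nested_cv <- function(features, sets = "PWA+PPI+SpO2", k = 5, seed = 1L,
                          num_trees = 100, rfecv = TRUE) {
  all_sets <- feature_sets()
  if (identical(sets, "all")) sets <- names(all_sets)
  stopifnot(all(sets %in% names(all_sets)))

  n_low <- sum(features$quality != "ok")
  data <- features[features$quality == "ok", , drop = FALSE]
  if (nrow(data) == 0) stop("no quality-ok segments", call. = FALSE)
  folds <- make_grouped_folds(data$subject_id, k = k, seed = seed)
  fmap <- setNames(folds$fold, folds$subject_id)
  data$fold <- as.integer(fmap[data$subject_id])

  preds <- list()
  fold_meta <- list()
  importances <- list()
  for (set_name in sets) {
    cols <- intersect(all_sets[[set_name]], names(data))
    for (f in sort(unique(data$fold))) {
      train <- data[data$fold != f, , drop = FALSE]
      test <- data[data$fold == f, , drop = FALSE]
      seed_f <- derive_seed(seed, paste0("outer_", set_name), f)
      selected <- if (rfecv) {
        select_features_rfecv(train, cols, seed = seed_f,
                              num_trees = num_trees)
      } else cols
      balanced <- undersample(train, seed = seed_f)
      model <- tune_and_train(balanced, selected, seed = seed_f)
      rf <- fit_rf(as.matrix(balanced[, selected, drop = FALSE]),
                   balanced$label, seed = seed_f, num_trees = num_trees)
      imp <- rf$variable.importance
      imp <- imp / sum(imp)
      p <- predict(model, test)
      preds[[length(preds) + 1L]] <- dplyr::bind_cols(
        test[, c("subject_id", "start", "label", "arousal")], p,
        tibble::tibble(fold = f, feature_set = set_name))
      fold_meta[[length(fold_meta) + 1L]] <- tibble::tibble(
        feature_set = set_name, fold = f,
        n_train = nrow(train), n_test = nrow(test),
        n_selected = length(selected),
        selected = list(as.character(selected)),
        cost = model$cost, kernel = model$kernel, inner_auc = model$cv_auc)
      importances[[length(importances) + 1L]] <- tibble::tibble(
        feature_set = set_name, fold = f,
        feature = names(imp), importance = as.numeric(imp))
    }
  }
  subjects <- dplyr::distinct(features, .data$subject_id)
  structure(
    list(predictions = dplyr::bind_rows(preds),
         folds = dplyr::bind_rows(fold_meta),
         importances = dplyr::bind_rows(importances),
         n_low_quality = n_low,
         seed = seed),
    class = "oxi_cv"
  )
}

#' @export
print.oxi_cv <- function(x, ...) {
  cat("<oxi_cv> nested cross-validation:",
      length(unique(x$folds$feature_set)), "feature set(s),",
      max(x$folds$fold), "outer folds,",
      nrow(x$predictions), "held-out predictions\n")
  invisible(x)
}
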