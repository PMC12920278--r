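# Metrics arithmetic, AHI estimation, screening decisions, severity bins,
# feature importance.

test_that("segment metrics reproduce confusion-matrix arithmetic", {
  y <- c(rep("positive", 22), rep("negative", 78))
  perfect <- segment_metrics(y, y, score = ifelse(y == "positive", 1, -1))
  expect_equal(perfect$accuracy, 100)
  expect_equal(perfect$sensitivity, 100)
  expect_equal(perfect$specificity, 100)
  expect_equal(perfect$precision, 100)
  expect_equal(perfect$auc, 1)

  all_neg <- segment_metrics(rep("negative", 100), y)
  expect_equal(all_neg$specificity, 100)
  expect_equal(all_neg$sensitivity, 0)
  expect_equal(all_neg$accuracy, 78)
  expect_true(is.na(all_neg$precision))

  set.seed(13)
  rand <- segment_metrics(rep("negative", 1000),
                          sample(c("positive", "negative"), 1000, TRUE),
                          score = rnorm(1000))
  expect_gt(rand$auc, 0.45)
  expect_lt(rand$auc, 0.55)
})

test_that("internal AUC agrees with pROC on random scores", {
  skip_if_not_installed("pROC")
  set.seed(14)
  y <- sample(c("positive", "negative"), 300, TRUE)
  s <- rnorm(300) + 0.8 * (y == "positive")
  ours <- oxipulse:::auc_score(s, y)
  theirs <- as.numeric(pROC::auc(pROC::roc(
    response = y, predictor = s, levels = c("negative", "positive"),
    direction = "<", quiet = TRUE)))
  expect_equal(ours, theirs, tolerance = 1e-12)
})

test_that("arousal-stratified recall decomposes overall recall", {
  set.seed(15)
  label <- sample(c("positive", "negative"), 400, TRUE, prob = c(0.3, 0.7))
  arousal <- runif(400) < 0.4
  pred <- ifelse(label == "positive" & (arousal | runif(400) < 0.5),
                 "positive", "negative")
  strat <- arousal_stratified_detection(pred, label, arousal)
  expect_equal(strat$recall_pct[strat$stratum == "with_arousal"], 100)
  overall <- 100 * sum(pred == "positive" & label == "positive") /
    sum(label == "positive")
  weighted <- sum(strat$detected) / sum(strat$n_positive) * 100
  expect_equal(weighted, overall)
  expect_true(all(strat$recall_pct >= 0 & strat$recall_pct <= 100))

  # desaturation-only detector: arousal-only positives invisible
  empty <- arousal_stratified_detection(rep("negative", 4),
                                        rep("positive", 4),
                                        rep(TRUE, 4))
  expect_true(is.na(empty$recall_pct[empty$stratum == "no_arousal"]))
})

test_that("AHI estimation is positive segments per recording hour", {
  expect_equal(estimate_ahi(rep("negative", 60), 1), 0)
  expect_equal(estimate_ahi(rep("positive", 60), 1), 60)
  expect_equal(estimate_ahi(c(rep("positive", 30), rep("negative", 420)), 7.5),
               4)
  expect_error(estimate_ahi("positive", 0), "positive number")
})

test_that("severity classes follow the clinical AHI bins", {
  expect_equal(as.character(severity_class(c(0, 4.9, 5, 14.9, 15, 30, 30.01, 31))),
               c("none", "none", "mild", "mild", "moderate", "moderate",
                 "severe", "severe"))
  expect_error(severity_class(-1), "non-negative")
})

test_that("screening decisions, confusion matrix and strata are consistent", {
  subj <- tibble::tibble(
    subject_id = sprintf("S%02d", 1:10),
    ref_ahi = c(2, 8, 12, 14, 16, 18, 22, 30, 40, 55),
    est_ahi = c(2, 8, 12, 14, 16, 18, 22, 30, 40, 55),
    comorbidity = rep(c(TRUE, FALSE), 5)
  )
  s <- screen_subjects(subj, stratum = "comorbidity")
  expect_equal(s$summary$sensitivity[1], 100)
  expect_equal(s$summary$specificity[1], 100)
  expect_equal(s$summary$pearson_r[1], 1)
  expect_equal(sum(s$confusion), 10)
  # stratum cells sum to stratum sizes
  expect_equal(sum(s$summary$n[-1]), 10)

  # systematic underestimation turns borderline positives into misses
  under <- dplyr::mutate(subj, est_ahi = ref_ahi - 5)
  su <- screen_subjects(under)
  borderline <- sum(subj$ref_ahi >= 15 & subj$ref_ahi < 20)
  expect_equal(su$summary$fn[1], borderline)
  expect_equal(su$summary$sensitivity[1],
               100 * (6 - borderline) / 6)

  # threshold boundary: estimate exactly 15 is positive
  s15 <- screen_subjects(tibble::tibble(subject_id = "a", est_ahi = 15,
                                        ref_ahi = 20))
  expect_true(s15$subjects$decision)
})

test_that("raising the screening threshold trades sensitivity for specificity", {
  set.seed(16)
  subj <- tibble::tibble(subject_id = sprintf("S%02d", 1:40),
                         ref_ahi = runif(40, 0, 50))
  subj$est_ahi <- pmax(0, subj$ref_ahi + rnorm(40, 0, 6))
  sens <- spec <- numeric(0)
  for (thr in c(5, 15, 30)) {
    s <- screen_subjects(subj, threshold = thr)
    sens <- c(sens, s$summary$sensitivity[1])
    spec <- c(spec, s$summary$specificity[1])
  }
  expect_true(all(diff(sens) <= 0))
  expect_true(all(diff(spec) >= 0))
})

test_that("feature importance ranks a planted effect first", {
  df <- make_planted_table(effect = 3, seed = 25)
  df$inf2 <- rnorm(nrow(df))                    # keep a single planted effect
  fam <- feature_families()
  names(df)[names(df) == "inf1"] <- fam$SpO2[1]
  names(df)[names(df) == "inf2"] <- fam$SpO2[2]
  for (i in 1:8) {
    names(df)[names(df) == paste0("noise", i)] <- fam$PPI[i]
  }
  cv <- run_nested_cv(df, sets = "PWA+PPI+SpO2", k = 5, seed = 11,
                      rfecv = FALSE)
  imp <- feature_importance(cv)
  expect_equal(imp$feature[1], fam$SpO2[1])
  expect_true(all(imp$mean_importance >= 0))
  # planted feature beats every noise feature in at least 4 of 5 folds
  per_fold <- cv$importances
  wins <- sapply(1:5, function(f) {
    fi <- per_fold[per_fold$fold == f, ]
    fi$importance[fi$feature == fam$SpO2[1]] > max(fi$importance[fi$feature %in% fam$PPI[1:8]])
  })
  expect_gte(sum(wins), 4)
})

test_that("feature-set comparison utility returns ANOVA and pairwise p-values", {
  set.seed(17)
  fm <- tidyr::expand_grid(feature_set = c("SpO2", "PPI+SpO2", "PWA+PPI+SpO2"),
                           fold = 1:5)
  fm$auc <- 0.8 + 0.05 * (fm$feature_set != "SpO2") + rnorm(nrow(fm), 0, 0.01)
  cmp <- compare_feature_sets(fm, metric = "auc", reference = "SpO2")
  expect_lt(cmp$anova_p, 0.05)
  expect_equal(nrow(cmp$pairwise), 2)
  expect_true(all(cmp$pairwise$p_adj >= cmp$pairwise$p_value - 1e-12))
})
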