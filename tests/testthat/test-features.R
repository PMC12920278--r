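# The 37-feature catalogue, per-subject normalization, and the
# positive/negative discrimination the synthetic physiology should induce.

test_that("the feature census is exactly the 37 catalogued names", {
  fam <- feature_families()
  expect_length(feature_names(), 37)
  expect_equal(length(fam$PPI), 23)
  expect_equal(length(fam$PWA), 7)
  expect_equal(length(fam$SpO2), 7)
  expect_false(any(duplicated(feature_names())))

  sets <- feature_sets()
  expect_named(sets, c("SpO2", "PWA+SpO2", "PPI+SpO2", "PWA+PPI",
                       "PWA+PPI+SpO2"))
  expect_length(sets[["PWA+PPI+SpO2"]], 37)
  expect_length(sets[["PPI+SpO2"]], 30)
})

test_that("every quality-ok segment yields 37 finite features", {
  f <- extract_features(small_prep())
  ok <- f[f$quality == "ok", feature_names()]
  expect_gt(nrow(ok), 0)
  expect_true(all(is.finite(as.matrix(ok))))
  expect_true(all(feature_names() %in% names(f)))
  # normalized-unit identity and variance identity hold row-wise
  expect_equal(ok$LFnu + ok$HFnu, rep(1, nrow(ok)), tolerance = 1e-9)
  expect_equal(ok$Var_Sp, ok$Std_Sp^2, tolerance = 1e-12)
  expect_true(all(ok$pNN50 >= 0 & ok$pNN50 <= 100))
  expect_true(all(ok$pNN20 >= 0 & ok$pNN20 <= 100))
})

test_that("time-domain PPI features match hand enumeration", {
  const <- rep(1, 5)
  f <- ppi_time_features(const)
  expect_equal(f$SDNN, 0)
  expect_equal(f$RMSSD, 0)
  expect_equal(f$NN50, 0)
  expect_equal(f$Range_NN, 0)
  expect_equal(f$Mean_NN, 1)
  expect_equal(f$Max_PR, 60)
  expect_equal(f$Min_PR, 60)

  nn <- c(0.8, 0.86, 0.9, 0.86, 0.8)
  f2 <- ppi_time_features(nn)
  expect_equal(f2$NN50, 2)                  # |+60|, |-60| ms
  expect_equal(f2$pNN50, 50)
  expect_equal(f2$NN20, 4)
  expect_equal(f2$pNN20, 100)
  expect_equal(f2$Mean_NN, mean(nn))

  expect_error(ppi_time_features(c(1, 1)), ">= 5")
})

test_that("time-domain features match the naive oracle on random series", {
  set.seed(8)
  for (i in 1:10) {
    nn <- runif(20 + i, 0.6, 1.2)
    got <- ppi_time_features(nn)
    want <- brute_ppi_time(nn)
    expect_equal(got[names(want)], want, tolerance = 1e-12)
  }
})

test_that("scaling NN intervals scales the right features", {
  set.seed(9)
  nn <- runif(30, 0.7, 1.1)
  f1 <- ppi_time_features(nn)
  f2 <- ppi_time_features(2 * nn)
  for (v in c("Mean_NN", "SDNN", "RMSSD", "Range_NN", "SDSD")) {
    expect_equal(f2[[v]], 2 * f1[[v]], tolerance = 1e-12, info = v)
  }
  expect_equal(f2$CVNNI, f1$CVNNI, tolerance = 1e-12)
  expect_equal(f2$CVSD, f1$CVSD, tolerance = 1e-12)
})

test_that("PWA features respond to amplitude structure and scale", {
  u <- rep(1, 240)
  f <- pwa_features(rep(2, 50), u)
  expect_equal(f$Std_PWA, 0)
  expect_equal(f$CV_PWA, 0)
  expect_equal(f$Max_PWA, f$Min_PWA)

  set.seed(10)
  pwa <- runif(50, 0.5, 1.5)
  f1 <- pwa_features(pwa, u)
  f2 <- pwa_features(3 * pwa, u)
  expect_equal(f2$CV_PWA, f1$CV_PWA, tolerance = 1e-12)
  expect_equal(f2$Max_PWA, 3 * f1$Max_PWA)
})

test_that("SpO2 features capture desaturations", {
  const <- rep(97, 960)
  f <- spo2_features(const)
  expect_equal(f$Min_Sp, 97)
  expect_equal(f$Mean_Sp, 97)
  expect_equal(f$Std_Sp, 0)
  expect_equal(f$Disp_Sp, 0)

  t <- (seq_len(960) - 1) / 16
  desat <- 97 - 4 * exp(-0.5 * ((t - 30) / 6)^2)
  f2 <- spo2_features(desat)
  expect_lt(abs(f2$Min_Sp - 93), 0.05)
  expect_gt(f2$Var_Sp, 0)
  expect_equal(f2$Var_Sp, f2$Std_Sp^2, tolerance = 1e-12)
})

test_that("per-subject min-max normalization maps to [0,1] with rank preserved", {
  set.seed(11)
  df <- tibble::tibble(
    subject_id = rep(c("A", "B"), each = 10),
    quality = "ok",
    Min_PWA = c(runif(10), runif(10, 5, 9)),
    CV_PWA = rep(2, 20),                       # constant column
    Min_Sp = runif(20, 90, 97)
  )
  out <- normalize_per_subject(df, columns = c("Min_PWA", "CV_PWA"))
  for (s in c("A", "B")) {
    v <- out$Min_PWA[out$subject_id == s]
    expect_equal(min(v), 0)
    expect_equal(max(v), 1)
    expect_equal(order(v), order(df$Min_PWA[df$subject_id == s]))
  }
  expect_true(all(out$CV_PWA == 0))
  expect_identical(out$Min_Sp, df$Min_Sp)     # SpO2 left unscaled

  single <- df[c(1, 11:20), ]
  expect_error(normalize_per_subject(single, columns = "Min_PWA"), "single")
})

test_that("event-locked physiology separates positive and negative segments", {
  f <- study_features()
  ok <- f[f$quality == "ok", ]
  pos <- ok[ok$label == "positive", ]
  neg <- ok[ok$label == "negative", ]
  # at least 200 segments per class at study scale
  expect_gt(nrow(pos), 200)
  expect_gt(nrow(neg), 200)
  set.seed(12)
  pos <- pos[sample(nrow(pos), 200), ]
  neg <- neg[sample(nrow(neg), 200), ]
  for (v in c("Min_PWA", "CV_PWA", "RMSSD", "Var_Sp")) {
    p <- stats::wilcox.test(pos[[v]], neg[[v]])$p.value
    expect_lt(p, 0.01)
  }
})
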