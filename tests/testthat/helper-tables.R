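# Synthetic feature tables with planted informative columns, used by the
# modeling and evaluation tests.

make_planted_table <- function(n_subjects = 10, n_per = 30, n_noise = 8,
                               effect = 1.5, seed = 20) {
  set.seed(seed)
  subj <- rep(sprintf("P%02d", seq_len(n_subjects)), each = n_per)
  label <- ifelse(runif(n_subjects * n_per) < 0.35, "positive", "negative")
  y <- as.numeric(label == "positive")
  df <- tibble::tibble(subject_id = subj, start = seq_along(subj),
                       label = label, arousal = FALSE, quality = "ok",
                       inf1 = rnorm(length(y)) + effect * y,
                       inf2 = rnorm(length(y)) - effect * y)
  for (i in seq_len(n_noise)) df[[paste0("noise", i)]] <- rnorm(length(y))
  df
}

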