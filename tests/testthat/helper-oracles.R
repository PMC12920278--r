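# Independent brute-force oracles. These deliberately use plain double loops
# and naive counting so they share no code path with the package
# implementations they check.

brute_sampen <- function(x, m = 2, r_frac = 0.2) {
  n <- length(x)
  r <- r_frac * sd(x)
  count_matches <- function(mm) {
    n_tpl <- n - m               # both lengths use the same template range
    cnt <- 0L
    for (i in seq_len(n_tpl - 1)) {
      for (j in (i + 1):n_tpl) {
        d <- 0
        for (k in 0:(mm - 1)) {
          d <- max(d, abs(x[i + k] - x[j + k]))
        }
        if (d <= r) cnt <- cnt + 1L
      }
    }
    cnt
  }
  B <- count_matches(m)
  A <- count_matches(m + 1)
  if (A == 0 || B == 0) return(NA_real_)
  -log(A / B)
}

brute_fuzzen <- function(x, m = 2, r_frac = 0.2, n_exp = 2) {
  n <- length(x)
  r <- r_frac * sd(x)
  phi <- function(mm) {
    n_tpl <- n - m
    tot <- 0
    for (i in seq_len(n_tpl)) {
      for (j in seq_len(n_tpl)) {
        if (i == j) next
        ti <- x[i:(i + mm - 1)]
        tj <- x[j:(j + mm - 1)]
        ti <- ti - mean(ti)
        tj <- tj - mean(tj)
        d <- max(abs(ti - tj))
        tot <- tot + exp(-(d / r)^n_exp)
      }
    }
    tot / (n_tpl * (n_tpl - 1))
  }
  log(phi(m)) - log(phi(m + 1))
}

brute_dispen <- function(x, m = 2, cc = 6) {
  n <- length(x)
  y <- pnorm(x, mean(x), sd(x))
  z <- pmin(pmax(ceiling(y * cc), 1), cc)
  pats <- character(0)
  for (i in seq_len(n - m + 1)) {
    pats <- c(pats, paste(z[i:(i + m - 1)], collapse = "-"))
  }
  tab <- table(pats)
  p <- as.numeric(tab) / sum(tab)
  -sum(p * log(p)) / log(cc^m)
}

# naive HRV time-domain statistics via direct formulas
brute_ppi_time <- function(nn) {
  d <- numeric(0)
  for (i in 2:length(nn)) d <- c(d, nn[i] - nn[i - 1])
  list(
    Mean_NN = sum(nn) / length(nn),
    Max_PR = 60 / min(nn),
    Min_PR = 60 / max(nn),
    SDNN = sd(nn),
    CVNNI = sd(nn) / mean(nn),
    SDSD = sd(d),
    CVSD = sqrt(sum(d^2) / length(d)) / mean(nn),
    NN50 = sum(abs(d) > 0.05),
    pNN50 = 100 * sum(abs(d) > 0.05) / length(d),
    NN20 = sum(abs(d) > 0.02),
    pNN20 = 100 * sum(abs(d) > 0.02) / length(d),
    RMSSD = sqrt(sum(d^2) / length(d)),
    Range_NN = max(nn) - min(nn)
  )
}

# interval intersection by brute force on a fine grid (0.01 s resolution)
grid_overlap <- function(events, start, seg_len = 60, step = 0.01) {
  ts <- seq(start, start + seg_len - step, by = step)
  covered <- rep(FALSE, length(ts))
  for (i in seq_len(nrow(events))) {
    covered <- covered |
      (ts >= events$onset[i] & ts < events$onset[i] + events$duration[i])
  }
  sum(covered) * step
}
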