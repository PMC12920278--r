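# Entropy measures used as nonlinear irregularity features on PPI and SpO2
# series. All three quantify how often short patterns recur: low values mean
# regular, repetitive dynamics; high values mean irregularity.

embed_series <- function(x, m, delay = 1) {
  n <- length(x) - (m - 1) * delay
  if (n < 1) stop("series too short for embedding", call. = FALSE)
  idx <- outer(seq_len(n), (0:(m - 1)) * delay, "+")
  matrix(x[idx], nrow = n)
}

# Chebyshev distance matrix between all template pairs
cheb_dist <- function(tpl) {
  n <- nrow(tpl)
  d <- matrix(0, n, n)
  for (k in seq_len(ncol(tpl))) {
    d <- pmax(d, abs(outer(tpl[, k], tpl[, k], "-")))
  }
  d
}

#' Sample entropy
#'
#' SampEn(m, r) = -ln(A / B) where B counts template pairs of length `m`
#' within Chebyshev distance `r` (self-matches excluded) and A the same for
#' length `m + 1`. Templates of length `m` are truncated to the number of
#' `m + 1` templates so both counts run over the same range, the standard
#' convention.
#'
#' @param x Numeric series.
#' @param m Embedding dimension.
#' @param r Tolerance as a fraction of the series SD (or an absolute value
#'   when `r_absolute = TRUE`).
#' @param delay Embedding delay in samples.
#' @param r_absolute Interpret `r` as an absolute tolerance.
#' @return SampEn value; `0` for a constant series; `NA` when no template
#'   pair matches (undefined).
#' @export
sample_entropy <- function(x, m = 2, r = 0.2, delay = 1, r_absolute = FALSE) {
  if (length(x) < 10 * m) stop("series too short for sample entropy (need >= 10*m)",
                               call. = FALSE)
  s <- sd(x)
  if (!r_absolute) {
    if (s == 0) return(0)
    r <- r * s
  } else if (s == 0) {
    return(0)
  }
  n_tpl <- length(x) - m * delay          # number of (m+1)-templates
  tpl_m <- embed_series(x, m, delay)[seq_len(n_tpl), , drop = FALSE]
  tpl_m1 <- embed_series(x, m + 1, delay)
  dB <- cheb_dist(tpl_m)
  dA <- cheb_dist(tpl_m1)
  B <- (sum(dB <= r) - n_tpl) / 2
  A <- (sum(dA <= r) - n_tpl) / 2
  if (B == 0 || A == 0) return(NA_real_)
  -log(A / B)
}

#' Fuzzy entropy
#'
#' Like sample entropy, but each template is baseline-removed (its own mean
#' subtracted) and similarity is graded by the exponential membership
#' function `exp(-(d / r)^n_exp)` of the Chebyshev distance `d` instead of a
#' hard threshold.
#'
#' @inheritParams sample_entropy
#' @param n_exp Membership function exponent.
#' @return FuzzEn value; `0` for a constant series.
#' @export
fuzzy_entropy <- function(x, m = 2, r = 0.2, n_exp = 2, delay = 1,
                          r_absolute = FALSE) {
  if (length(x) < 10 * m) stop("series too short for fuzzy entropy (need >= 10*m)",
                               call. = FALSE)
  s <- sd(x)
  if (s == 0) return(0)
  if (!r_absolute) r <- r * s
  phi <- function(mm) {
    n_tpl <- length(x) - m * delay
    tpl <- embed_series(x, mm, delay)[seq_len(n_tpl), , drop = FALSE]
    tpl <- tpl - rowMeans(tpl)
    d <- cheb_dist(tpl)
    mu <- exp(-(d / r)^n_exp)
    (sum(mu) - n_tpl) / (n_tpl * (n_tpl - 1))
  }
  log(phi(m)) - log(phi(m + 1))
}

#' Dispersion entropy (normalized)
#'
#' The series is mapped through the normal CDF (fitted mean/SD) onto `c`
#' classes; the Shannon entropy of the frequencies of `m`-length dispersion
#' patterns is normalized by `log(c^m)` so the result lies in [0, 1].
#'
#' @inheritParams sample_entropy
#' @param c_classes Number of dispersion classes.
#' @return Normalized DispEn in [0, 1]; `0` for a constant series.
#' @export
dispersion_entropy <- function(x, m = 2, c_classes = 6, delay = 1) {
  if (length(x) < 10 * m) stop("series too short for dispersion entropy (need >= 10*m)",
                               call. = FALSE)
  s <- sd(x)
  if (s == 0) return(0)
  y <- pnorm(x, mean(x), s)
  z <- pmin(pmax(ceiling(y * c_classes), 1L), c_classes)
  pat <- embed_series(z, m, delay)
  code <- as.vector(pat %*% c_classes^(seq_len(m) - 1))
  p <- tabulate(match(code, unique(code)))
  p <- p / sum(p)
  -sum(p * log(p)) / log(c_classes^m)
}
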