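#' @importFrom stats approx fft median pnorm rnorm runif sd var
#'   predict aov cor p.adjust t.test setNames splinefun
#' @importFrom rlang .data
#' @importFrom utils head
NULL

# Derive a stage-specific seed from the global run seed so stages can be rerun
# in isolation. Stable across sessions (depends only on the stage string).
derive_seed <- function(seed, stage, index = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h * 131 + index) %% 2147483587) + 1L
}

# Rank-based (Mann-Whitney) AUC of scores against a binary truth vector.
# Ties in scores are handled by midranks. Returns NA if one class is absent.
auc_score <- function(scores, truth) {
  pos <- truth_to_logical(truth)
  n1 <- sum(pos)
  n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Accept "positive"/"negative", factor, or logical class encodings.
truth_to_logical <- function(x) {
  if (is.logical(x)) return(x)
  if (is.factor(x)) x <- as.character(x)
  if (is.character(x)) return(x == "positive")
  as.logical(x)
}

label_factor <- function(x) {
  factor(ifelse(truth_to_logical(x), "positive", "negative"),
         levels = c("negative", "positive"))
}

assert_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0) {
    stop(sprintf("`%s` must be a single positive number", name), call. = FALSE)
  }
  invisible(x)
}

assert_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("`%s` must be a single number in [0, 1]", name), call. = FALSE)
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
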