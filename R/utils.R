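#' Derive a child seed from a base seed and a tag
#'
#' All randomness in multi-stage procedures flows from one user-supplied base
#' seed; independent stages get distinct, reproducible child seeds so that
#' adding or reordering stages does not perturb unrelated draws.
#'
#' @param seed integer base seed.
#' @param tag character tag naming the consumer.
#' @return an integer seed in [1, 2^31 - 2].
#' @export
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(tag))
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  # modular mix; kept below .Machine$integer.max
  as.integer((abs(seed) %% 1000003L) * 2017L + (h %% 999983L) * 7L + 1L) %% 2147483646L + 1L
}

#' Clip values to an interval
#' @keywords internal
clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Mean of a Gaussian clipped (censored) to an interval
#'
#' Closed form for E[min(max(X, lo), hi)] with X ~ N(mean, sd). Used to state
#' the exact expectation of bounded simulated features (relative power, ITPC),
#' whose draws are clipped to their native range.
#'
#' @param mean,sd Gaussian parameters (sd >= 0).
#' @param lo,hi interval bounds.
#' @return the expectation of the clipped variable.
#' @export
clipped_normal_mean <- function(mean, sd, lo = 0, hi = 1) {
  if (sd == 0) return(clip(mean, lo, hi))
  a <- (lo - mean) / sd
  b <- (hi - mean) / sd
  # infinite bounds carry zero clipped mass; avoid Inf * 0 = NaN
  lo_term <- if (is.finite(lo)) lo * stats::pnorm(a) else 0
  hi_term <- if (is.finite(hi)) hi * stats::pnorm(-b) else 0
  lo_term + hi_term +
    mean * (stats::pnorm(b) - stats::pnorm(a)) +
    sd * (stats::dnorm(a) - stats::dnorm(b))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_fx <- function(...) stop(sprintf(...), call. = FALSE)
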