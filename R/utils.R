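#' @keywords internal
"_PACKAGE"

#' @useDynLib neurotactile, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif anova lm median sd aggregate
#' @importFrom utils head tail write.csv read.csv
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Centered moving average
#'
#' Boxcar moving mean with edge shrinkage (the window is truncated at the
#' series boundaries), matching the usual behaviour of MATLAB's `movmean`.
#'
#' @param x numeric vector.
#' @param k window length in samples (coerced to an odd integer >= 1).
#' @return numeric vector of the same length as `x`.
#' @export
moving_average <- function(x, k) {
  k <- max(1L, as.integer(k))
  if (k %% 2L == 0L) k <- k + 1L
  if (k == 1L || length(x) < 2L) return(x)
  n <- length(x)
  cs <- cumsum(c(0, x))
  h <- (k - 1L) %/% 2L
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Robust noise RMS estimate
#'
#' Median-absolute-deviation estimator of the noise standard deviation of an
#' extracellular trace (`median(|x|) / 0.6745`), insensitive to spikes.
#'
#' @param x numeric trace.
#' @return scalar noise RMS estimate in the units of `x`.
#' @export
estimate_noise_rms <- function(x) {
  stats::median(abs(x - stats::median(x))) / 0.6745
}

next_pow2 <- function(n) 2L^ceiling(log2(max(2, n)))

#' Derive a child seed from a base seed
#'
#' Deterministic 32-bit-safe seed derivation used to give every session of a
#' protocol its own independent random stream.
#'
#' @param base_seed integer base seed.
#' @param index positive integer index of the child stream.
#' @return integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(base_seed, index) {
  as.integer((as.numeric(base_seed) * 131 + 7919 * as.numeric(index)) %% 2147483646 + 1)
}

rms <- function(x) sqrt(mean(x^2))

stopifnot_finite <- function(x, what) {
  if (!all(is.finite(x))) stop("non-finite values in ", what, call. = FALSE)
  invisible(x)
}
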