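#' Evaluate an expression under a temporary RNG seed
#'
#' Saves the caller's RNG state, seeds the generator, evaluates `expr`, and
#' restores the previous state, so generator functions are pure in
#' `(args, seed)` without clobbering the session RNG.
#'
#' @param seed integer seed, or `NULL` to use the current RNG stream as-is.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)  # materialize .Random.seed
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

#' Causal discrete convolution with a kernel sampled at rate fs
#'
#' Approximates the continuous convolution `(x * k)(t)`: the discrete
#' convolution is scaled by the sample period, so a kernel with unit
#' continuous area (`sum(k)/fs == 1`) has unit DC gain. Returns the first
#' `length(x)` samples (causal alignment).
#'
#' @param x numeric signal.
#' @param k discrete kernel (samples of a continuous kernel at `fs`).
#' @param fs sampling rate in Hz.
#' @return numeric vector, same length as `x`.
#' @keywords internal
conv_causal <- function(x, k, fs) {
  n <- length(x)
  y <- stats::convolve(c(x, numeric(length(k))), rev(k), type = "open") / fs
  y[seq_len(n)]
}

#' Causal convolution with steady-state left edge
#'
#' As [conv_causal()] but the signal is extended to the left with its first
#' value before convolving, so slowly varying signals are not attenuated
#' during the kernel warm-up interval.
#' @inheritParams conv_causal
#' @keywords internal
conv_steady <- function(x, k, fs) {
  m <- length(k)
  xp <- c(rep(x[1], m), x)
  y <- stats::convolve(c(xp, numeric(m)), rev(k), type = "open") / fs
  y[m + seq_along(x)]
}

#' Gaussian smoothing of a series
#'
#' Convolution with a unit-sum discrete Gaussian window (truncated at
#' 4 sigma), reflect-padded so edges are unbiased.
#'
#' @param x numeric series.
#' @param sigma_s Gaussian standard deviation in seconds.
#' @param fs sampling rate (Hz).
#' @return smoothed series, same length as `x`.
#' @keywords internal
gauss_smooth <- function(x, sigma_s, fs) {
  if (sigma_s <= 0) return(x)
  half <- max(1L, ceiling(4 * sigma_s * fs))
  t <- (-half:half) / fs
  g <- exp(-0.5 * (t / sigma_s)^2)
  g <- g / sum(g)
  n <- length(x)
  # reflect-pad (clamped for very short inputs) so edges stay unbiased
  left <- x[pmin(n, pmax(1L, 1L + (half:1L)))]
  right <- x[pmin(n, pmax(1L, n - (1L:half)))]
  xp <- c(left, x, right)
  y <- stats::filter(xp, g, method = "convolution", sides = 2)
  as.numeric(y[half + seq_len(n)])
}

stop_if_not <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}

# centered sliding minimum / maximum (window of `w` samples, edge-clamped)
run_min <- function(x, w) {
  half <- max(1L, floor(w / 2))
  n <- length(x)
  out <- x
  for (k in seq_len(half)) {
    out <- pmin(out, c(x[(k + 1):n], rep(x[n], k)), c(rep(x[1], k), x[1:(n - k)]))
  }
  out
}

run_max <- function(x, w) -run_min(-x, w)
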