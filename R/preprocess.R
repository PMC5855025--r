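#' Butterworth low-pass design as second-order sections
#'
#' Designs an order-`n` digital Butterworth low-pass (bilinear transform of
#' the analog prototype) and returns it as a cascade of biquads. A
#' second-order-section cascade stays numerically well conditioned at high
#' orders, where the expanded transfer-function polynomial does not.
#'
#' @param order filter order (positive integer).
#' @param cutoff -3 dB cutoff frequency in Hz.
#' @param fs sampling rate in Hz; `cutoff` must be below `fs/2`.
#' @return list of sections, each `list(b = c(b0, b1, b2), a = c(1, a1, a2))`
#'   (first-order sections have `b2 = a2 = 0` for odd orders). Each section
#'   has exact unit DC gain.
#' @keywords internal
butter_lowpass_sos <- function(order, cutoff, fs) {
  stop_if_not(order >= 1 && order == round(order), "`order` must be a positive integer")
  stop_if_not(cutoff > 0 && cutoff < fs / 2,
              "`cutoff` must lie strictly below the Nyquist frequency fs/2")
  wa <- tan(pi * cutoff / fs)  # prewarped analog cutoff (T = 2 convention)
  # analog prototype poles on the unit circle, scaled to wa; keep one of each
  # conjugate pair
  k <- seq_len(floor(order / 2))
  theta <- pi * (2 * k - 1) / (2 * order) + pi / 2
  poles <- wa * exp(1i * theta)
  sos <- lapply(poles, function(p) {
    c1 <- -2 * Re(p)        # s^2 + c1 s + c0, gain c0
    c0 <- Mod(p)^2
    a0 <- 1 + c1 + c0
    list(b = c0 * c(1, 2, 1) / a0,
         a = c(1, (2 * c0 - 2) / a0, (1 - c1 + c0) / a0))
  })
  if (order %% 2 == 1) {                # real pole at -wa
    a0 <- 1 + wa
    sos <- c(sos, list(list(b = wa * c(1, 1, 0) / a0,
                            a = c(1, (wa - 1) / a0, 0))))
  }
  sos
}

# single biquad, direct form via FIR part + C-level recursive filter
sos_filter_one <- function(sec, x) {
  n <- length(x)
  b <- sec$b; a <- sec$a
  v <- b[1] * x +
    b[2] * c(0, x[-n]) +
    b[3] * c(0, 0, x[-c(n - 1, n)])
  as.numeric(stats::filter(v, -a[2:3], method = "recursive"))
}

#' Zero-phase filtering through a second-order-section cascade
#'
#' Applies each section forward and backward (squared magnitude response,
#' zero phase). The signal is extended at both ends by odd reflection so
#' start-up transients die out in the extension, not in the data.
#'
#' @param sos section list from [butter_lowpass_sos()].
#' @param x numeric signal.
#' @param padlen extension length in samples (default 300, capped at n-1).
#' @return filtered signal, same length as `x`.
#' @keywords internal
sosfiltfilt <- function(sos, x, padlen = 300L) {
  n <- length(x)
  minlen <- 3L * (2L * length(sos) + 1L)
  stop_if_not(n > minlen,
              sprintf("signal too short for zero-phase filtering (need > %d samples)", minlen))
  pad <- min(as.integer(padlen), n - 1L)
  xp <- c(2 * x[1] - x[(pad + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - pad)])
  for (sec in sos) {
    xp <- sos_filter_one(sec, xp)
    xp <- rev(sos_filter_one(sec, rev(xp)))
  }
  xp[pad + seq_len(n)]
}

#' Low-pass filter a GSR recording
#'
#' Order-10 Butterworth low-pass below 20 Hz by default, removing
#' high-frequency noise, motion and EMG artifacts picked up at the wrist.
#' The filter is applied forward and backward (zero phase) so skin
#' conductance response onset latencies are not shifted.
#'
#' @param rec a [gsr_recording()].
#' @param cutoff cutoff frequency in Hz (default 20); must be below `fs/2`.
#' @param order Butterworth order (default 10).
#' @return the filtered [gsr_recording()] (same length and rate).
#' @examples
#' rec <- gsr_recording(4 + rnorm(2000, sd = 0.05), fs = 200)
#' filt <- lowpass_filter(rec)
#' @export
lowpass_filter <- function(rec, cutoff = 20, order = 10) {
  stopifnot(inherits(rec, "gsr_recording"))
  sos <- butter_lowpass_sos(order, cutoff, rec$fs)
  y <- sosfiltfilt(sos, rec$samples)
  gsr_recording(y, rec$fs, rec$subject_id, rec$condition)
}

#' Resample a recording to the working rate
#'
#' Integer downsampling is done by sample picking (the preceding low-pass is
#' the anti-alias stage); non-integer ratios and upsampling fall back to
#' linear interpolation on the time grid, which is documented behavior, not
#' silent truncation.
#'
#' @param rec a [gsr_recording()].
#' @param fs_out target rate in Hz (default 50, the working rate of all
#'   downstream analysis).
#' @return resampled [gsr_recording()].
#' @export
resample_to <- function(rec, fs_out = 50) {
  stopifnot(inherits(rec, "gsr_recording"))
  stop_if_not(fs_out > 0, "`fs_out` must be positive")
  if (fs_out == rec$fs) return(rec)
  ratio <- rec$fs / fs_out
  n <- length(rec$samples)
  if (ratio >= 1 && abs(ratio - round(ratio)) < 1e-9) {
    y <- rec$samples[seq(1L, n, by = as.integer(round(ratio)))]
  } else {
    t_in <- (seq_len(n) - 1) / rec$fs
    t_out <- seq(0, t_in[n], by = 1 / fs_out)
    y <- stats::approx(t_in, rec$samples, xout = t_out)$y
  }
  gsr_recording(y, fs_out, rec$subject_id, rec$condition)
}

#' Preprocess a raw recording
#'
#' Convenience wrapper: [lowpass_filter()] then [resample_to()], the fixed
#' order of operations (the low-pass doubles as the anti-alias filter).
#'
#' @inheritParams lowpass_filter
#' @inheritParams resample_to
#' @return preprocessed [gsr_recording()] at `fs_out`.
#' @export
preprocess <- function(rec, cutoff = 20, order = 10, fs_out = 50) {
  resample_to(lowpass_filter(rec, cutoff, order), fs_out)
}
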