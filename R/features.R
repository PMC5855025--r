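#' Segment a signal into overlapping analysis windows
#'
#' Fixed 5 s windows with 4 s overlap by default (1 s hop), the short-term
#' segmentation used for low-latency distraction identification. A trailing
#' partial window is dropped, so a `T`-second signal yields
#' `floor((T - win_s) / hop) + 1` windows.
#'
#' @param x numeric signal (phasic conductance).
#' @param fs sampling rate (Hz).
#' @param win_s window length, seconds (default 5).
#' @param overlap_s overlap between consecutive windows, seconds (default 4;
#'   must be < `win_s`).
#' @param subject_id,condition labels copied onto every window.
#' @return list of `gsr_window` objects (`samples`, `fs`, `start_s`,
#'   `subject_id`, `condition`).
#' @examples
#' length(segment(rnorm(6000), fs = 50))  # 120 s -> 116 windows
#' @export
segment <- function(x, fs, win_s = 5, overlap_s = 4,
                    subject_id = NA_character_, condition = NA_character_) {
  stop_if_not(overlap_s < win_s, "`overlap_s` must be smaller than `win_s`")
  stop_if_not(win_s > 0 && fs > 0, "window length and fs must be positive")
  wlen <- round(win_s * fs)
  stop_if_not(length(x) >= wlen, "signal shorter than one window")
  hop <- round((win_s - overlap_s) * fs)
  starts <- seq(1L, length(x) - wlen + 1L, by = hop)
  lapply(starts, function(s0) {
    structure(list(samples = x[s0:(s0 + wlen - 1L)], fs = fs,
                   start_s = (s0 - 1) / fs, subject_id = subject_id,
                   condition = condition),
              class = "gsr_window")
  })
}

#' Window moment features (f1-f5)
#'
#' Mean, population variance, accumulated GSR (window sum divided by the
#' full task duration -- which is what distinguishes it from the mean),
#' maximum, and power (mean squared sample).
#'
#' @param x numeric window samples.
#' @param total_task_s full recording duration in seconds (> 0), the
#'   accumulated-GSR denominator.
#' @return named numeric vector `f1_mean, f2_variance, f3_accumulated,
#'   f4_max, f5_power`.
#' @export
basic_stats <- function(x, total_task_s) {
  stop_if_not(total_task_s > 0, "`total_task_s` must be positive")
  m <- mean(x)
  c(f1_mean = m,
    f2_variance = mean((x - m)^2),
    f3_accumulated = sum(x) / total_task_s,
    f4_max = max(x),
    f5_power = mean(x^2))
}

#' Derivative-based peak detection (f6, f7)
#'
#' Stride-2 first and second differences of the window,
#' `Q0(i) = |P(i+1) - P(i-1)|` and `Q1(i) = |P(i+2) - 2 P(i) + P(i-2)|`, are
#' combined as `Q2 = 1.3 Q0 + 1.1 Q1` and scanned against a threshold. Each
#' maximal contiguous run with `Q2 >= threshold` counts as one peak whose
#' amplitude is the maximum sample inside the run.
#'
#' The printed threshold (1.0) presumes a particular conductance scale;
#' phasic amplitudes are scale-dependent, so the threshold is exposed.
#'
#' @param x numeric window samples (length >= 5).
#' @param threshold scan threshold on `Q2` (default 1.0).
#' @return a `peak_scan` list: `q0`, `q1`, `q2` (aligned to samples
#'   `3 .. n-2`), `threshold`, `peak_regions` (two-column index matrix in
#'   original sample coordinates), `n_peaks` (f6), `sum_amplitudes` (f7).
#' @export
detect_peaks <- function(x, threshold = 1.0) {
  n <- length(x)
  stop_if_not(n >= 5, "window must have at least 5 samples")
  i <- 3:(n - 2)
  q0 <- abs(x[i + 1] - x[i - 1])
  q1 <- abs(x[i + 2] - 2 * x[i] + x[i - 2])
  q2 <- 1.3 * q0 + 1.1 * q1
  r <- rle(q2 >= threshold)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  regions <- cbind(start = i[starts[keep]], end = i[ends[keep]])
  amps <- if (nrow(regions)) {
    vapply(seq_len(nrow(regions)),
           function(j) max(x[regions[j, 1]:regions[j, 2]]), numeric(1))
  } else numeric(0)
  structure(list(q0 = q0, q1 = q1, q2 = q2, threshold = threshold,
                 peak_regions = regions, n_peaks = nrow(regions),
                 sum_amplitudes = sum(amps)),
            class = "peak_scan")
}

#' Short-time Fourier band powers (f8-f11)
#'
#' Hann-windowed short-time Fourier transform over 1 s sub-windows with
#' 0.5 s overlap; the magnitude-squared spectrum is averaged over time and
#' then within four equal-width bands spanning 0 to `fs/2` (6.25 Hz bands at
#' the 50 Hz working rate).
#'
#' @param x numeric window samples.
#' @param fs sampling rate (Hz).
#' @param n_bands number of bands (default 4).
#' @param sub_win_s,sub_overlap_s sub-window length and overlap, seconds.
#' @return named numeric vector `f8_stft1 .. f11_stft4` (band mean powers).
#' @export
stft_band_features <- function(x, fs, n_bands = 4, sub_win_s = 1.0,
                               sub_overlap_s = 0.5) {
  wlen <- round(sub_win_s * fs)
  hop <- round((sub_win_s - sub_overlap_s) * fs)
  stop_if_not(wlen >= 4 && hop >= 1 && length(x) >= wlen,
              "window too short for the requested STFT sub-windows")
  win <- 0.5 - 0.5 * cos(2 * pi * seq(0, wlen - 1) / (wlen - 1))  # Hann
  starts <- seq(1L, length(x) - wlen + 1L, by = hop)
  nbin <- floor(wlen / 2) + 1L
  psd <- rowMeans(vapply(starts, function(s0) {
    seg <- x[s0:(s0 + wlen - 1L)] * win
    Mod(stats::fft(seg)[seq_len(nbin)])^2
  }, numeric(nbin)))
  band <- pmin(n_bands, 1L + floor((seq_len(nbin) - 1) / ((nbin) / n_bands)))
  out <- vapply(seq_len(n_bands), function(b) mean(psd[band == b]), numeric(1))
  names(out) <- sprintf("f%d_stft%d", 7 + seq_len(n_bands), seq_len(n_bands))
  out
}

#' Higuchi fractal dimension (f12)
#'
#' Standard Higuchi construction: mean normalized curve length `L(k)` over
#' decimated sub-series for `k = 1..kmax`; the fractal dimension is the
#' slope of `log(L(k))` against `log(1/k)`. Near 1 for smooth curves, near 2
#' for white noise; invariant to amplitude scaling.
#'
#' @param x numeric series (length > 2 * kmax).
#' @param kmax maximum delay (default 8).
#' @return scalar fractal dimension estimate.
#' @export
higuchi_fd <- function(x, kmax = 8) {
  n <- length(x)
  stop_if_not(n > 2 * kmax, "`kmax` too large for this window")
  lk <- vapply(seq_len(kmax), function(k) {
    lm_ <- vapply(seq_len(k), function(m) {
      idx <- seq(m, n, by = k)
      if (length(idx) < 2) return(NA_real_)
      norm <- (n - 1) / ((length(idx) - 1) * k)
      sum(abs(diff(x[idx]))) * norm / k
    }, numeric(1))
    mean(lm_, na.rm = TRUE)
  }, numeric(1))
  if (any(lk <= 0)) return(1.0)  # flat (zero-length) curve
  stats::coef(stats::lm(log(lk) ~ log(1 / seq_len(kmax))))[[2]]
}

#' Katz fractal dimension (f13)
#'
#' `D = log10(n) / (log10(n) + log10(d / L))` with `n` the number of steps,
#' `L` the total absolute path length and `d` the maximum absolute deviation
#' from the first sample. Exactly 1 for a monotone line; defined as 1 (with
#' a warning) for a constant series, whose path length is zero.
#'
#' @param x numeric series (length >= 2).
#' @return scalar fractal dimension.
#' @export
katz_fd <- function(x) {
  stop_if_not(length(x) >= 2, "need at least 2 samples")
  steps <- abs(diff(x))
  L <- sum(steps)
  d <- max(abs(x - x[1]))
  if (L == 0 || d == 0) {
    warning("constant series: Katz fractal dimension defined as 1")
    return(1.0)
  }
  n <- length(steps)
  log10(n) / (log10(n) + log10(d / L))
}

#' Burg autoregressive coefficients (f14-f18)
#'
#' Order-`p` AR coefficients `a(1..p)` of the mean-removed window in the
#' convention `y(n) = sum_k a(k) y(n-k) + e(n)`, estimated by the Burg
#' method (stable on short windows). A window with zero variance returns all
#' zeros.
#'
#' @param x numeric window samples (length > 2 * p).
#' @param p model order (default 5).
#' @return named numeric vector `f14_ar1 .. f18_ar5` (for `p = 5`).
#' @export
ar_coefficients <- function(x, p = 5) {
  stop_if_not(length(x) > 2 * p, "window too short for AR order p")
  a <- if (stats::var(x) <= .Machine$double.eps) {
    numeric(p)
  } else {
    fit <- stats::ar.burg(x, aic = FALSE, order.max = p, demean = TRUE)
    as.numeric(fit$ar)
  }
  names(a) <- sprintf("f%d_ar%d", 13 + seq_len(p), seq_len(p))
  a
}

#' Extract the 18-dimensional feature vector of one window
#'
#' Fixed order: f1 mean, f2 variance, f3 accumulated GSR, f4 maximum,
#' f5 power, f6 number of peaks, f7 summed peak amplitudes, f8-f11 STFT band
#' powers, f12 Higuchi FD, f13 Katz FD, f14-f18 Burg AR(5) coefficients.
#'
#' @param w a `gsr_window` from [segment()].
#' @param total_task_s full recording duration, seconds.
#' @param peak_threshold threshold for [detect_peaks()].
#' @param kmax Higuchi delay bound.
#' @return named numeric vector of length 18 with attributes `subject_id`,
#'   `condition`, `start_s`, or `NULL` (with a warning) if any feature fails.
#' @export
extract_features <- function(w, total_task_s, peak_threshold = 1.0, kmax = 8) {
  stopifnot(inherits(w, "gsr_window"))
  v <- tryCatch({
    pk <- detect_peaks(w$samples, peak_threshold)
    kfd <- withCallingHandlers(
      katz_fd(w$samples),
      warning = function(cnd) invokeRestart("muffleWarning"))
    c(basic_stats(w$samples, total_task_s),
      f6_n_peaks = pk$n_peaks,
      f7_sum_peak_amp = pk$sum_amplitudes,
      stft_band_features(w$samples, w$fs),
      f12_higuchi_fd = higuchi_fd(w$samples, kmax),
      f13_katz_fd = kfd,
      ar_coefficients(w$samples))
  }, error = function(e) {
    warning(sprintf("window at %.1f s skipped: %s", w$start_s,
                    conditionMessage(e)))
    NULL
  })
  if (is.null(v)) return(NULL)
  if (!all(is.finite(v))) {
    warning(sprintf("window at %.1f s skipped: non-finite feature", w$start_s))
    return(NULL)
  }
  attr(v, "subject_id") <- w$subject_id
  attr(v, "condition") <- w$condition
  attr(v, "start_s") <- w$start_s
  v
}

#' Feature names in canonical order
#' @return character vector of the 18 feature column names.
#' @export
feature_names <- function() {
  c("f1_mean", "f2_variance", "f3_accumulated", "f4_max", "f5_power",
    "f6_n_peaks", "f7_sum_peak_amp", "f8_stft1", "f9_stft2", "f10_stft3",
    "f11_stft4", "f12_higuchi_fd", "f13_katz_fd",
    sprintf("f%d_ar%d", 14:18, 1:5))
}

#' Windowed feature table for one decomposition
#'
#' Segments the phasic conductance of a decomposition and extracts the 18
#' features per window.
#'
#' @param dec an [decompose()] result (or any object with `sc_phasic`,
#'   `fs`, `subject_id`, `condition`).
#' @param win_s,overlap_s segmentation controls (see [segment()]).
#' @param peak_threshold peak-scan threshold; the pipeline default (0.004)
#'   matches the conductance scale of the synthetic generator.
#' @param kmax Higuchi delay bound.
#' @return data.frame with the 18 feature columns plus `subject_id`,
#'   `condition`, `window_start_s`.
#' @export
feature_table <- function(dec, win_s = 5, overlap_s = 4,
                          peak_threshold = 0.004, kmax = 8) {
  wins <- segment(dec$sc_phasic, dec$fs, win_s, overlap_s,
                  dec$subject_id, dec$condition)
  total_s <- length(dec$sc_phasic) / dec$fs
  rows <- lapply(wins, extract_features, total_task_s = total_s,
                 peak_threshold = peak_threshold, kmax = kmax)
  keep <- !vapply(rows, is.null, logical(1))
  df <- as.data.frame(do.call(rbind, rows[keep]))
  names(df) <- feature_names()
  df$subject_id <- vapply(rows[keep], attr, character(1), "subject_id")
  df$condition <- vapply(rows[keep], attr, character(1), "condition")
  df$window_start_s <- vapply(rows[keep], attr, numeric(1), "start_s")
  df
}

#' Smoothed pseudo Wigner-Ville spectrogram
#'
#' Quadratic time-frequency energy map of the analytic signal, with
#' independent frequency (Hann on the lag axis) and time (boxcar) smoothing
#' to attenuate cross-terms. The frequency axis is normalized to 0-1 (1 is
#' the Nyquist frequency `fs/2`), and the map is scaled so its total energy
#' matches the signal energy `sum(x^2)`.
#'
#' @param x numeric signal (length >= 64).
#' @param fs sampling rate (Hz).
#' @param lag_half half-length of the lag window (frequency smoothing);
#'   default `min(64, floor((n-1)/2))`.
#' @param time_smooth_s boxcar time-smoothing length, seconds (default 0.1).
#' @param hop time step between evaluated columns, samples (default 1).
#' @return a `tf_map` list: `matrix` (frequency x time), `time_axis` (s),
#'   `freq_axis` (normalized 0-1).
#' @export
wvd_spectrogram <- function(x, fs, lag_half = NULL, time_smooth_s = 0.1,
                            hop = 1L) {
  n <- length(x)
  stop_if_not(n >= 64, "signal too short for a time-frequency map")
  if (is.null(lag_half)) lag_half <- min(64L, floor((n - 1) / 2))
  # analytic signal via the frequency domain
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  z <- stats::fft(X * h, inverse = TRUE) / n
  # time smoothing of the instantaneous autocorrelation
  g_half <- max(0L, round(time_smooth_s * fs / 2))
  K <- 2L * lag_half + 1L
  lagwin <- 0.5 + 0.5 * cos(pi * (-lag_half:lag_half) / lag_half)  # Hann, w(0)=1
  cols <- seq(1L, n, by = as.integer(hop))
  W <- matrix(0, nrow = K, ncol = length(cols))
  for (ci in seq_along(cols)) {
    tt <- cols[ci]
    r <- complex(length.out = K)
    for (m in -lag_half:lag_half) {
      g0 <- (-g_half):g_half
      ii <- tt + g0 + m
      jj <- tt + g0 - m
      ok <- ii >= 1 & ii <= n & jj >= 1 & jj <= n
      if (any(ok)) {
        r[m + lag_half + 1L] <- mean(z[ii[ok]] * Conj(z[jj[ok]])) *
          lagwin[m + lag_half + 1L]
      }
    }
    # shift lags so m = 0 is first, then DFT over the lag axis
    W[, ci] <- Re(stats::fft(r[c((lag_half + 1L):K, 1L:lag_half)]))
  }
  # per column, sum over freq bins of DFT(r)/K equals r(0) = |z(t)|^2; the
  # analytic signal carries twice the real-signal energy, so divide by 2 to
  # make total map energy approximate sum(x^2)
  W <- W / K / 2
  # the instantaneous autocorrelation of a tone at f0 oscillates at 2*f0/fs
  # cycles per lag sample, so DFT bin k directly reads normalized frequency
  # f0/(fs/2) = k/K in [0, 1)
  structure(list(matrix = W,
                 time_axis = (cols - 1) / fs,
                 freq_axis = (seq_len(K) - 1) / K),
            class = "tf_map")
}
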