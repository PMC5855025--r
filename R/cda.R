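#' Bateman impulse-response parameters
#'
#' The biexponential impulse response `exp(-t/tau2) - exp(-t/tau1)` shapes a
#' single skin conductance response: a fast rise governed by `tau1` and a
#' slow recovery governed by `tau2`. Defaults are the canonical continuous
#' decomposition initial values (1.0 s / 3.75 s).
#'
#' @param tau1 rise time constant, seconds (`0 < tau1 < tau2`).
#' @param tau2 decay time constant, seconds.
#' @param kernel_len_s truncation length of the discrete kernel, seconds
#'   (>= `5 * tau2` so the truncated tail is negligible).
#' @return an `irf_params` object.
#' @export
irf_params <- function(tau1 = 1.0, tau2 = 3.75, kernel_len_s = 5 * tau2) {
  stop_if_not(tau1 > 0, "`tau1` must be positive")
  stop_if_not(tau1 < tau2, "need tau1 < tau2 (biexponential would degenerate)")
  stop_if_not(kernel_len_s >= 5 * tau2, "`kernel_len_s` must be >= 5 * tau2")
  structure(list(tau1 = tau1, tau2 = tau2, kernel_len_s = kernel_len_s),
            class = "irf_params")
}

#' Discrete Bateman impulse response
#'
#' Samples `exp(-t/tau2) - exp(-t/tau1)` on `t = 0, 1/fs, ...,
#' kernel_len_s`, normalized to unit continuous area (`sum(k)/fs == 1`), so
#' convolution via [conv_causal()] has unit DC gain and driver units are
#' preserved. `k[1] == 0` by construction.
#'
#' @param params an [irf_params()].
#' @param fs sampling rate in Hz.
#' @return numeric kernel vector.
#' @examples
#' k <- bateman_irf(irf_params(), fs = 50)
#' sum(k) / 50  # unit area
#' @export
bateman_irf <- function(params, fs) {
  stopifnot(inherits(params, "irf_params"))
  stop_if_not(fs > 0, "`fs` must be positive")
  t <- seq(0, params$kernel_len_s, by = 1 / fs)
  k <- exp(-t / params$tau2) - exp(-t / params$tau1)
  k / (sum(k) / fs)
}

#' Deconvolve skin conductance by the impulse response
#'
#' Frequency-domain division with Tikhonov regularization:
#' `D = FFT(sc) * Conj(K) / (|K|^2 + reg * max |K|^2)`. Before the FFT the
#' signal is extended by a smooth half-cosine bridge (at least two kernel
#' lengths) running from its last back to its first sample, so the implied
#' circular signal has no jump for the inverse filter to amplify; for a
#' signal that starts and ends at zero this reduces to plain zero-padding
#' and the division is exact. Deconvolution amplifies high-frequency error,
#' which is why the resulting driver is Gaussian-smoothed downstream
#' ([decompose()]).
#'
#' @param sc conductance series (longer than the kernel).
#' @param irf discrete kernel from [bateman_irf()].
#' @param fs sampling rate (Hz).
#' @param reg regularization weight, relative to the peak squared spectrum
#'   magnitude (default 1e-4; use ~0 only for noiseless round-trips).
#' @return estimated total driver, same length as `sc`.
#' @export
deconvolve <- function(sc, irf, fs, reg = 1e-4) {
  stop_if_not(length(sc) > length(irf), "`sc` must be longer than the kernel")
  stop_if_not(any(irf != 0), "IRF is identically zero")
  n <- length(sc)
  m <- length(irf)
  L <- stats::nextn(n + 2L * m, c(2L, 3L))
  u <- seq_len(L - n) / (L - n + 1)
  bridge <- sc[n] + (sc[1] - sc[n]) * (1 - cos(pi * u)) / 2
  xp <- c(sc, bridge)
  K <- stats::fft(c(irf, numeric(L - m)))
  X <- stats::fft(xp)
  denom <- Mod(K)^2 + reg * max(Mod(K)^2)
  D <- X * Conj(K) / denom
  d <- Re(stats::fft(D, inverse = TRUE)) / L * fs
  d[seq_len(n)]
}

#' Estimate the tonic driver between phasic impulses
#'
#' In the driver domain phasic responses are compressed to short impulses,
#' so stretches between impulses expose the tonic level. The estimate is
#' built by (a) Gaussian-smoothing the total driver, (b) masking impulse-free
#' samples -- those within `peak_thresh` of a morphological-opening baseline
#' (running minimum then maximum over `open_s`, which rides under impulses
#' while following slow drift), (c) placing one support point per
#' `grid_spacing_s` cell at the masked minimum of the inter-impulse
#' interval, and (d) interpolating the support points with a natural cubic
#' spline.
#'
#' @param driver_total total driver series (finite).
#' @param fs sampling rate (Hz).
#' @param smooth_sigma_s Gaussian smoothing width, seconds (default 0.2).
#' @param grid_spacing_s spline grid spacing, seconds (default 5).
#' @param peak_thresh driver-unit margin above the opening baseline below
#'   which a sample counts as impulse-free (default 0.05).
#' @param open_s opening window length, seconds (default 3; wider than a
#'   smoothed impulse, narrower than tonic variation).
#' @return tonic driver series, same length as `driver_total`.
#' @export
estimate_tonic_driver <- function(driver_total, fs, smooth_sigma_s = 0.2,
                                  grid_spacing_s = 5, peak_thresh = 0.05,
                                  open_s = 3) {
  stop_if_not(all(is.finite(driver_total)), "`driver_total` must be finite")
  n <- length(driver_total)
  s <- gauss_smooth(driver_total, smooth_sigma_s, fs)
  t <- (seq_len(n) - 1) / fs
  base <- run_max(run_min(s, round(open_s * fs)), round(open_s * fs))
  free_mask <- s <= base + peak_thresh
  cell <- floor(t / grid_spacing_s)
  cells <- sort(unique(cell))
  grid_t <- numeric(0)
  grid_v <- numeric(0)
  for (cl in cells) {
    idx <- which(cell == cl)
    if (length(idx) < 2) next
    free <- idx[free_mask[idx]]
    if (!length(free)) next
    j <- free[which.min(s[free])]
    grid_t <- c(grid_t, t[j])
    grid_v <- c(grid_v, s[j])
  }
  if (length(grid_t) < 2) {
    warning("no impulse-free intervals found; falling back to a global percentile baseline")
    return(rep(stats::quantile(s, 0.1, names = FALSE), n))
  }
  # anchor the ends so the spline does not extrapolate
  if (grid_t[1] > 0) { grid_t <- c(0, grid_t); grid_v <- c(grid_v[1], grid_v) }
  ng <- length(grid_t)
  if (grid_t[ng] < t[n]) { grid_t <- c(grid_t, t[n]); grid_v <- c(grid_v, grid_v[ng]) }
  stats::spline(grid_t, grid_v, xout = t, method = "natural")$y
}

#' Continuous decomposition of a skin conductance recording
#'
#' Splits conductance into tonic and phasic drivers: the total driver is
#' recovered by regularized deconvolution against the Bateman impulse
#' response and Gaussian-smoothed; the tonic driver is estimated from
#' inter-impulse intervals ([estimate_tonic_driver()]); the phasic driver is
#' their difference, a near-zero-baseline impulse train. Tonic and phasic
#' conductance are the drivers re-convolved with the impulse response, so
#' `sc_tonic + sc_phasic` reconstructs the input (the reconstruction error
#' is checked on every call).
#'
#' @param rec a preprocessed [gsr_recording()] (at the working rate).
#' @param params an [irf_params()].
#' @param reg deconvolution regularization (see [deconvolve()]).
#' @param smooth_sigma_s Gaussian smoothing of the driver, seconds.
#' @param grid_spacing_s,peak_thresh tonic-estimation controls, see
#'   [estimate_tonic_driver()].
#' @param recon_tol relative RMS reconstruction error above which a warning
#'   is emitted (default 0.01).
#' @return an `sc_decomposition` object: `sc`, `driver_total`,
#'   `driver_tonic`, `driver_phasic`, `sc_tonic`, `sc_phasic`, `fs`,
#'   `recon_error`, plus the recording labels.
#' @examples
#' syn <- synthesize_recording(synth_config(duration_s = 60, seed = 3),
#'                             default_profiles()$text)
#' dec <- decompose(preprocess(syn$recording))
#' dec
#' @export
decompose <- function(rec, params = irf_params(), reg = 1e-4,
                      smooth_sigma_s = 0.2, grid_spacing_s = 10,
                      peak_thresh = 0.05, recon_tol = 0.01) {
  stopifnot(inherits(rec, "gsr_recording"))
  irf <- bateman_irf(params, rec$fs)
  driver_raw <- deconvolve(rec$samples, irf, rec$fs, reg)
  driver_total <- gauss_smooth(driver_raw, smooth_sigma_s, rec$fs)
  driver_tonic <- estimate_tonic_driver(driver_total, rec$fs, smooth_sigma_s,
                                        grid_spacing_s, peak_thresh)
  driver_phasic <- driver_total - driver_tonic
  sc_tonic <- conv_steady(driver_tonic, irf, rec$fs)
  sc_phasic <- conv_steady(driver_phasic, irf, rec$fs)
  recon <- sc_tonic + sc_phasic
  recon_error <- sqrt(mean((recon - rec$samples)^2)) /
    sqrt(mean(rec$samples^2))
  if (recon_error > recon_tol) {
    warning(sprintf("decomposition reconstruction error %.3g exceeds %.3g",
                    recon_error, recon_tol))
  }
  structure(
    list(sc = rec$samples, driver_total = driver_total,
         driver_tonic = driver_tonic, driver_phasic = driver_phasic,
         sc_tonic = sc_tonic, sc_phasic = sc_phasic, fs = rec$fs,
         subject_id = rec$subject_id, condition = rec$condition,
         recon_error = recon_error),
    class = "sc_decomposition"
  )
}

#' @export
print.sc_decomposition <- function(x, ...) {
  cat(sprintf(
    "<sc_decomposition> subject=%s condition=%s  %d samples @ %g Hz\n",
    x$subject_id, x$condition, length(x$sc), x$fs))
  cat(sprintf("  tonic level: %.3f uS (mean);  phasic driver baseline (median): %.4f\n",
              mean(x$sc_tonic), stats::median(x$driver_phasic)))
  cat(sprintf("  reconstruction rel. RMS error: %.2e\n", x$recon_error))
  invisible(x)
}

#' Write a decomposition as CSV
#'
#' Columns: `time_s, sc, driver_total, driver_tonic, driver_phasic,
#' sc_tonic, sc_phasic`.
#'
#' @param dec an [decompose()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_decomposition_csv <- function(dec, path) {
  n <- length(dec$sc)
  df <- data.frame(time_s = (seq_len(n) - 1) / dec$fs, sc = dec$sc,
                   driver_total = dec$driver_total,
                   driver_tonic = dec$driver_tonic,
                   driver_phasic = dec$driver_phasic,
                   sc_tonic = dec$sc_tonic, sc_phasic = dec$sc_phasic)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
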