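#' Condition profile for the synthetic EDA generator
#'
#' Describes the sudomotor impulse statistics of one driving condition.
#' Distraction shows up in electrodermal activity as denser trains and
#' bursts of skin conductance responses (SCRs), so distracted profiles carry
#' higher impulse rates and burst probabilities than the normal-driving one.
#'
#' @param name condition label, one of `"normal"`, `"phone"`, `"text"`.
#' @param impulse_rate mean SCR impulses per second (> 0 unless exactly 0,
#'   which yields an empty driver).
#' @param burst_prob probability in \[0, 1\] that an impulse spawns a burst of
#'   2--4 closely spaced impulses (0.5--1.5 s apart), the overlapping-SCR
#'   regime deconvolution exists to untangle.
#' @param amp_shape,amp_scale shape/scale of the Gamma distribution of
#'   impulse amplitudes, in driver units (microsiemens x 1/s integrated area
#'   of the sudomotor impulse).
#' @return a `condition_profile` object.
#' @seealso [default_profiles()]
#' @export
condition_profile <- function(name, impulse_rate, burst_prob,
                              amp_shape = 2, amp_scale = 0.3) {
  name <- match.arg(name, c("normal", "phone", "text"))
  stop_if_not(impulse_rate >= 0, "`impulse_rate` must be >= 0")
  stop_if_not(burst_prob >= 0 && burst_prob <= 1, "`burst_prob` must be in [0, 1]")
  stop_if_not(amp_shape > 0 && amp_scale > 0, "Gamma parameters must be positive")
  structure(list(name = name, impulse_rate = impulse_rate,
                 burst_prob = burst_prob, amp_shape = amp_shape,
                 amp_scale = amp_scale),
            class = "condition_profile")
}

#' Default condition profiles
#'
#' The three driving conditions emulated by the generator. Normal driving is
#' sparse (one SCR every ~20 s, rarely bursting); phone and text distraction
#' have progressively denser, burstier phasic activity, with texting
#' (cognitive + visual load) the densest.
#'
#' @return named list of [condition_profile()] objects
#'   (`normal`, `phone`, `text`).
#' @export
default_profiles <- function() {
  list(
    normal = condition_profile("normal", impulse_rate = 0.05, burst_prob = 0.1),
    phone  = condition_profile("phone",  impulse_rate = 0.25, burst_prob = 0.4),
    text   = condition_profile("text",   impulse_rate = 0.35, burst_prob = 0.5)
  )
}

#' Synthetic-recording configuration
#'
#' Parameters of the electrodermal emulation: raw sampling rate, recording
#' length, Bateman impulse-response time constants, tonic level and drift,
#' and measurement noise.
#'
#' @param fs_raw raw device sampling rate in Hz (default 200).
#' @param duration_s recording length in seconds (default 120, i.e. ~2 min
#'   per driving task).
#' @param tau1,tau2 rise and decay time constants (s) of the biexponential
#'   SCR impulse response; `tau1 < tau2`.
#' @param tonic_base tonic skin conductance level in microsiemens (> 0).
#' @param tonic_drift_sd scale (microsiemens) of the slow tonic drift.
#' @param noise_sd additive white measurement noise, microsiemens (>= 0).
#' @param seed integer RNG seed.
#' @return a `synth_config` object.
#' @export
synth_config <- function(fs_raw = 200, duration_s = 120, tau1 = 1.0,
                         tau2 = 3.75, tonic_base = 4, tonic_drift_sd = 0.3,
                         noise_sd = 0.01, seed = 1L) {
  stop_if_not(fs_raw > 0, "`fs_raw` must be positive")
  stop_if_not(duration_s > 0, "`duration_s` must be positive")
  stop_if_not(tau1 > 0 && tau1 < tau2, "need 0 < tau1 < tau2")
  stop_if_not(tonic_base > 0, "`tonic_base` must be positive")
  stop_if_not(noise_sd >= 0, "`noise_sd` must be >= 0")
  structure(list(fs_raw = fs_raw, duration_s = duration_s, tau1 = tau1,
                 tau2 = tau2, tonic_base = tonic_base,
                 tonic_drift_sd = tonic_drift_sd, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' Generate a sparse phasic (sudomotor) driver
#'
#' Homogeneous Poisson impulse train with optional bursts: each primary
#' impulse spawns, with probability `burst_prob`, 1--3 extra impulses spaced
#' Uniform(0.5, 1.5) s apart, giving bursts of 2--4 overlapping SCRs.
#' Amplitudes are Gamma-distributed. The returned series is the driver
#' sampled at `fs`: an impulse of amplitude `a` contributes one sample of
#' height `a * fs`, so its discrete-time integral is `a`.
#'
#' @param profile a [condition_profile()].
#' @param duration_s recording length in seconds (> 0).
#' @param fs sampling rate in Hz (> 0).
#' @param seed integer seed, or `NULL` to draw from the current RNG stream.
#' @return list with `driver` (numeric series, nonnegative and sparse),
#'   `impulse_times` (sorted, seconds) and `impulse_amps`.
#' @export
generate_phasic_driver <- function(profile, duration_s, fs, seed = NULL) {
  stopifnot(inherits(profile, "condition_profile"))
  stop_if_not(duration_s > 0, "`duration_s` must be positive")
  stop_if_not(fs > 0, "`fs` must be positive")
  with_seed(seed, {
    n_primary <- stats::rpois(1, profile$impulse_rate * duration_s)
    times <- sort(stats::runif(n_primary, 0, duration_s))
    if (n_primary > 0 && profile$burst_prob > 0) {
      extra <- unlist(lapply(times, function(t0) {
        if (stats::runif(1) < profile$burst_prob) {
          n_extra <- sample(1:3, 1)
          t0 + cumsum(stats::runif(n_extra, 0.5, 1.5))
        } else numeric(0)
      }))
      times <- sort(c(times, extra[extra < duration_s]))
    }
    amps <- if (length(times)) {
      stats::rgamma(length(times), shape = profile$amp_shape,
                    scale = profile$amp_scale)
    } else numeric(0)
    n <- round(duration_s * fs)
    driver <- numeric(n)
    if (length(times)) {
      idx <- pmin(n, floor(times * fs) + 1L)
      for (j in seq_along(idx)) driver[idx[j]] <- driver[idx[j]] + amps[j] * fs
    }
    list(driver = driver, impulse_times = times, impulse_amps = amps)
  })
}

#' Generate a slowly drifting tonic level
#'
#' Sum of a constant base and a handful of low-frequency sinusoids
#' (0.005--0.04 Hz) with normalized amplitudes, so the series is band-limited
#' below 0.05 Hz by construction and its derivative is bounded by
#' `drift_sd * 2 * pi * 0.04` microsiemens per second.
#'
#' @param duration_s length in seconds.
#' @param fs sampling rate (Hz).
#' @param base tonic level, microsiemens (> 0).
#' @param drift_sd drift scale, microsiemens (`0` gives a constant series).
#' @param seed integer seed or `NULL`.
#' @return numeric tonic series of length `round(duration_s * fs)`.
#' @export
generate_tonic <- function(duration_s, fs, base = 4, drift_sd = 0.3,
                           seed = NULL) {
  stop_if_not(base > 0, "`base` must be positive")
  stop_if_not(duration_s > 0 && fs > 0, "duration and fs must be positive")
  n <- round(duration_s * fs)
  t <- (seq_len(n) - 1) / fs
  if (drift_sd == 0) return(rep(base, n))
  with_seed(seed, {
    k <- 6L
    f <- stats::runif(k, 0.005, 0.04)
    ph <- stats::runif(k, 0, 2 * pi)
    a <- stats::runif(k, 0.5, 1)
    a <- a / sum(a)
    drift <- drift_sd * colSums(a * sin(outer(2 * pi * f, t) + ph))
    base + drift
  })
}

#' Synthesize one labeled GSR recording with ground truth
#'
#' Skin conductance is composed per the convolution model of electrodermal
#' activity: `SC = tonic + driver_phasic * IRF + noise`, with the Bateman
#' impulse response shared with the decomposition stage.
#'
#' @param config a [synth_config()]; `config$seed` makes the recording a pure
#'   function of `(config, profile)`.
#' @param profile a [condition_profile()].
#' @param subject_id label carried into the recording.
#' @return list with `recording` (a [gsr_recording()] at `fs_raw`) and
#'   `truth` (list: `impulse_times`, `impulse_amps`, `tonic_truth`,
#'   `phasic_truth`, `driver`, `fs`) -- the simulated ground-truth
#'   decomposition.
#' @examples
#' syn <- synthesize_recording(synth_config(duration_s = 30, seed = 7),
#'                             default_profiles()$phone)
#' syn$recording
#' @export
synthesize_recording <- function(config, profile, subject_id = "S1") {
  stopifnot(inherits(config, "synth_config"), inherits(profile, "condition_profile"))
  fs <- config$fs_raw
  with_seed(config$seed, {
    tonic <- generate_tonic(config$duration_s, fs, config$tonic_base,
                            config$tonic_drift_sd, seed = NULL)
    drv <- generate_phasic_driver(profile, config$duration_s, fs, seed = NULL)
    irf <- bateman_irf(irf_params(config$tau1, config$tau2), fs)
    phasic <- conv_causal(drv$driver, irf, fs)
    noise <- if (config$noise_sd > 0) {
      stats::rnorm(length(tonic), sd = config$noise_sd)
    } else 0
    sc <- tonic + phasic + noise
    list(
      recording = gsr_recording(sc, fs, subject_id, profile$name),
      truth = list(impulse_times = drv$impulse_times,
                   impulse_amps = drv$impulse_amps,
                   tonic_truth = tonic, phasic_truth = phasic,
                   driver = drv$driver, fs = fs)
    )
  })
}

#' Generate a labeled synthetic cohort
#'
#' One recording per subject x condition (3 per subject). Subjects get
#' random tonic bases (Uniform(2, 8) microsiemens) and a subject-specific
#' impulse-rate multiplier (Uniform(0.8, 1.2)), emulating the
#' subject-dependence of tonic level and sudomotor reactivity.
#'
#' @param n_subjects number of subjects (>= 1; default 10).
#' @param config a [synth_config()]; `config$seed` is the master seed.
#' @param profiles named list of the three [condition_profile()]s.
#' @return a `gsr_cohort`: list of entries, each with `recording` and
#'   `truth` as in [synthesize_recording()].
#' @export
generate_cohort <- function(n_subjects = 10, config = synth_config(),
                            profiles = default_profiles()) {
  stop_if_not(n_subjects >= 1, "`n_subjects` must be >= 1")
  entries <- with_seed(config$seed, {
    bases <- stats::runif(n_subjects, 2, 8)
    rate_mult <- stats::runif(n_subjects, 0.8, 1.2)
    seeds <- sample.int(.Machine$integer.max - 1L, n_subjects * length(profiles))
    out <- vector("list", n_subjects * length(profiles))
    i <- 0L
    for (s in seq_len(n_subjects)) {
      for (p in profiles) {
        i <- i + 1L
        prof_s <- condition_profile(p$name, p$impulse_rate * rate_mult[s],
                                    p$burst_prob, p$amp_shape, p$amp_scale)
        cfg_s <- config
        cfg_s$tonic_base <- bases[s]
        cfg_s$seed <- seeds[i]
        out[[i]] <- synthesize_recording(cfg_s, prof_s,
                                         subject_id = sprintf("S%02d", s))
      }
    }
    out
  })
  structure(entries, class = "gsr_cohort")
}

#' @export
print.gsr_cohort <- function(x, ...) {
  subj <- vapply(x, function(e) e$recording$subject_id, character(1))
  cond <- vapply(x, function(e) e$recording$condition, character(1))
  cat(sprintf("<gsr_cohort> %d recordings, %d subjects\n",
              length(x), length(unique(subj))))
  print(table(condition = cond))
  invisible(x)
}

#' Write a cohort to disk
#'
#' One `eda_uS` CSV per recording, per-recording ground-truth CSV
#' (`tonic_truth`, `phasic_truth`) and JSON (impulse times/amplitudes), plus
#' a `manifest.json` indexing all files.
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if missing).
#' @return the manifest path, invisibly.
#' @export
write_cohort_csv <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- lapply(cohort, function(e) {
    rec <- e$recording
    stem <- sprintf("%s_%s", rec$subject_id, rec$condition)
    sig <- file.path(dir, paste0(stem, ".csv"))
    write_recording_csv(rec, sig)
    gt_csv <- file.path(dir, paste0(stem, "_truth.csv"))
    utils::write.csv(data.frame(tonic_truth = e$truth$tonic_truth,
                                phasic_truth = e$truth$phasic_truth),
                     gt_csv, row.names = FALSE)
    gt_json <- file.path(dir, paste0(stem, "_impulses.json"))
    jsonlite::write_json(list(impulse_times = e$truth$impulse_times,
                              impulse_amps = e$truth$impulse_amps),
                         gt_json, digits = NA)
    list(subject = rec$subject_id, condition = rec$condition,
         signal = basename(sig), truth_csv = basename(gt_csv),
         truth_json = basename(gt_json))
  })
  mpath <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, pretty = TRUE)
  invisible(mpath)
}
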