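# Shared fixtures: small, fast synthetic objects built in code.

fast_config <- function(seed = 1, duration_s = 60, noise_sd = 0.01) {
  synth_config(fs_raw = 200, duration_s = duration_s, noise_sd = noise_sd,
               seed = seed)
}

# a preprocessed decomposition of one synthetic recording
fixture_decomposition <- function(condition = "text", seed = 3,
                                  duration_s = 60, noise_sd = 0.01) {
  syn <- synthesize_recording(fast_config(seed, duration_s, noise_sd),
                              default_profiles()[[condition]])
  suppressWarnings(decompose(preprocess(syn$recording)))
}

# rebuild a ground-truth driver on the 50 Hz working grid and smooth it the
# way the decomposition smooths its driver
truth_driver_50 <- function(syn, n_out, sigma_s = 0.2) {
  tr <- numeric(n_out)
  ii <- pmin(n_out, floor(syn$truth$impulse_times * 50) + 1L)
  for (j in seq_along(ii)) tr[ii[j]] <- tr[ii[j]] + syn$truth$impulse_amps[j] * 50
  gsrdistract:::gauss_smooth(tr, sigma_s, 50)
}

# literal brute-force implementation of the derivative peak scan, used as an
# independent oracle for detect_peaks
oracle_peaks <- function(p, threshold = 1.0) {
  n <- length(p)
  q2 <- rep(NA_real_, n)
  for (i in 3:(n - 2)) {
    q0 <- abs(p[i + 1] - p[i - 1])
    q1 <- abs(p[i + 2] - 2 * p[i] + p[i - 2])
    q2[i] <- 1.3 * q0 + 1.1 * q1
  }
  above <- !is.na(q2) & q2 >= threshold
  n_peaks <- 0L
  amps <- numeric(0)
  i <- 1L
  while (i <= n) {
    if (above[i]) {
      j <- i
      while (j < n && above[j + 1L]) j <- j + 1L
      n_peaks <- n_peaks + 1L
      amps <- c(amps, max(p[i:j]))
      i <- j + 1L
    } else i <- i + 1L
  }
  list(n_peaks = n_peaks, sum_amplitudes = sum(amps))
}

# brute-force re-implementation of the recursive-elimination loop, kept
# deliberately naive; mirrors the shipped tie-break rules
oracle_rfe <- function(X, y, C = 1) {
  X <- as.matrix(X)
  y <- factor(y)
  remaining <- seq_len(ncol(X))
  order_out <- integer(0)
  while (length(remaining) > 1) {
    Xs <- X[, remaining, drop = FALSE]
    mu <- colMeans(Xs)
    sg <- apply(Xs, 2, stats::sd)
    const <- sg == 0
    sg[const] <- 1
    Xs <- sweep(sweep(Xs, 2, mu), 2, sg, "/")
    Xs[, const] <- 0
    fit <- e1071::svm(Xs, y, kernel = "linear", cost = C, scale = FALSE)
    w <- as.numeric(t(fit$coefs) %*% fit$SV)
    crit <- w^2
    crit[const] <- -Inf
    worst <- max(which(crit == min(crit)))
    order_out <- c(order_out, remaining[worst])
    remaining <- remaining[-worst]
  }
  rev(c(order_out, remaining))
}

# planted-signal cohort for consensus-recovery tests: 7 informative features
# with graded within-class noise (population property, shared by subjects),
# 11 pure-noise features
planted_cohort_ranks <- function(n_subjects = 10, n_windows = 250,
                                 sds = c(0.08, 0.13, 0.19, 0.26, 0.34, 0.43, 0.53)) {
  inf <- c(6, 9, 13, 14, 15, 17, 18)
  t(sapply(seq_len(n_subjects), function(s) {
    y <- rep(c("normal", "phone"), each = n_windows / 2)
    X <- matrix(stats::rnorm(n_windows * 18), n_windows, 18)
    for (j in seq_along(inf)) {
      X[, inf[j]] <- as.numeric(y == "phone") + stats::rnorm(n_windows, sd = sds[j])
    }
    svm_rfe_rank(X, y)
  }))
}

informative_set <- function() c(6, 9, 13, 14, 15, 17, 18)
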