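test_that("segmentation window counts follow the closed form", {
  expect_length(segment(numeric(6000), fs = 50), 116)   # 120 s -> 116 windows
  expect_length(segment(numeric(250), fs = 50), 1)      # exactly 5 s
  expect_error(segment(numeric(245), fs = 50), "shorter")
  expect_error(segment(numeric(500), fs = 50, win_s = 5, overlap_s = 5),
               "smaller")
  w <- segment(rnorm(400), fs = 50)   # 8 s -> 4 windows
  expect_equal(vapply(w, `[[`, numeric(1), "start_s"), c(0, 1, 2, 3))
  expect_true(all(vapply(w, function(x) length(x$samples), numeric(1)) == 250))
})

test_that("moment features match hand arithmetic", {
  f <- basic_stats(c(1, 2, 3), total_task_s = 120)
  expect_equal(unname(f), c(2, 2 / 3, 6 / 120, 3, 14 / 3))
  expect_equal(unname(basic_stats(numeric(10), 60)), rep(0, 5))
  fc <- basic_stats(rep(2, 10), 60)
  expect_equal(unname(fc[c("f2_variance", "f5_power")]), c(0, 4))
  expect_error(basic_stats(1:3, total_task_s = 0), "positive")
})

test_that("peak detection agrees with the literal derivative-scan oracle", {
  # constructed cases
  expect_equal(detect_peaks(rep(1, 100))$n_peaks, 0)
  fs <- 50
  irf <- bateman_irf(irf_params(), fs)
  # one SCR scaled so the rising edge clearly exceeds the scan threshold but
  # the recovery tail stays below it (one contiguous run)
  unit <- irf[1:400] / max(irf)
  q2max <- max(detect_peaks(unit, threshold = Inf)$q2)
  scr <- 2.5 / q2max * unit
  got <- detect_peaks(scr, threshold = 1)
  want <- oracle_peaks(scr, 1)
  expect_equal(got$n_peaks, 1)
  expect_equal(got$sum_amplitudes, want$sum_amplitudes)
  expect_gt(got$sum_amplitudes, 0.5 * max(scr))
  # two SCRs >= 6 s apart on a continuous base -> two runs
  d <- numeric(800)
  d[c(50, 400)] <- 2.5 / q2max * fs / max(irf)
  two <- gsrdistract:::conv_causal(d, irf, fs)
  got2 <- detect_peaks(two, threshold = 1)
  expect_equal(got2$n_peaks, 2)
  expect_equal(got2$sum_amplitudes, oracle_peaks(two, 1)$sum_amplitudes)
  expect_error(detect_peaks(c(1, 2, 3)), "at least 5")

  # oracle equivalence on 1000 random windows
  set.seed(99)
  for (i in 1:1000) {
    p <- cumsum(rnorm(60, sd = 0.5))
    thr <- sample(c(0.5, 1, 2), 1)
    got <- detect_peaks(p, thr)
    want <- oracle_peaks(p, thr)
    expect_identical(got$n_peaks, want$n_peaks)
    expect_equal(got$sum_amplitudes, want$sum_amplitudes)
  }
})

test_that("the combined scan array obeys its definition", {
  p <- cumsum(rnorm(40))
  ps <- detect_peaks(p, 1)
  expect_equal(ps$q2, 1.3 * ps$q0 + 1.1 * ps$q1)
})

test_that("STFT band powers localize tones and vanish on silence", {
  fs <- 50
  expect_equal(unname(stft_band_features(numeric(250), fs)), rep(0, 4))
  tone <- sin(2 * pi * 3 * (0:249) / fs)
  f <- stft_band_features(tone, fs)
  expect_gt(f[1], 10 * max(f[-1]))
  # flat spectrum: four bands agree within 20% on average over seeds
  set.seed(3)
  bands <- rowMeans(replicate(100, stft_band_features(rnorm(250), fs)))
  expect_lt(max(bands) / min(bands), 1.2)
})

test_that("Higuchi fractal dimension hits its benchmark values", {
  line <- seq(0, 1, length.out = 250)
  expect_lt(abs(higuchi_fd(line) - 1), 0.05)
  set.seed(4)
  noise_fd <- mean(vapply(1:50, function(s) higuchi_fd(rnorm(250)), numeric(1)))
  expect_lt(abs(noise_fd - 2), 0.15)
  x <- rnorm(250)
  expect_lt(abs(higuchi_fd(x) - higuchi_fd(3 * x)), 1e-9)
  expect_error(higuchi_fd(rnorm(10), kmax = 8), "kmax")
})

test_that("Katz fractal dimension follows its formula on constructed curves", {
  expect_identical(katz_fd(seq(1, 5, length.out = 100)), 1.0)
  expect_warning(kc <- katz_fd(rep(2, 50)), "constant")
  expect_identical(kc, 1.0)
  # triangle wave: independent direct evaluation of the formula
  tri <- rep(c(0, 1), 50)[1:100]
  L <- sum(abs(diff(tri)))
  d <- max(abs(tri - tri[1]))
  want <- log10(99) / (log10(99) + log10(d / L))
  expect_equal(katz_fd(tri), want)
  expect_error(katz_fd(1), "2 samples")
})

test_that("Burg AR coefficients recover planted processes", {
  set.seed(12)
  x1 <- as.numeric(stats::arima.sim(list(ar = 0.5), 5000))
  a1 <- ar_coefficients(x1)
  expect_lt(abs(a1[1] - 0.5), 0.05)
  expect_lt(max(abs(a1[2:5])), 0.1)

  a_true <- c(0.5, -0.3, 0.2, -0.1, 0.05)
  x5 <- as.numeric(stats::arima.sim(list(ar = a_true), 5000))
  expect_lt(max(abs(ar_coefficients(x5) - a_true)), 0.05)

  wn <- rowMeans(replicate(50, abs(ar_coefficients(rnorm(500)))))
  expect_lt(max(wn), 0.1)

  expect_equal(unname(ar_coefficients(rep(1, 100))), rep(0, 5))
  expect_error(ar_coefficients(rnorm(8), p = 5), "too short")
})

test_that("feature vectors have the 18 documented fields and sane edge cases", {
  w <- segment(rnorm(250, sd = 0.1), fs = 50, subject_id = "S1",
               condition = "text")[[1]]
  v <- extract_features(w, total_task_s = 120)
  expect_length(v, 18)
  expect_identical(names(v), feature_names())
  expect_true(all(is.finite(v)))
  expect_identical(attr(v, "condition"), "text")
  expect_identical(v, extract_features(w, total_task_s = 120))  # deterministic

  wz <- segment(numeric(250), fs = 50)[[1]]
  vz <- extract_features(wz, total_task_s = 120)
  expect_equal(unname(vz[1:11]), rep(0, 11))
  expect_equal(unname(vz["f13_katz_fd"]), 1)
  expect_equal(unname(vz[14:18]), rep(0, 5))
})

test_that("cohort window bookkeeping matches the closed-form count", {
  dec <- fixture_decomposition(seed = 2, duration_s = 60)
  ft <- feature_table(dec)
  expect_equal(nrow(ft), floor((60 - 5) / 1) + 1)
  expect_true(all(feature_names() %in% names(ft)))
})

test_that("mean peak count increases from normal through phone to text", {
  means <- vapply(c("normal", "phone", "text"), function(cond) {
    mean(vapply(1:20, function(s) {
      dec <- fixture_decomposition(cond, seed = 100 + s, duration_s = 60)
      mean(feature_table(dec)$f6_n_peaks)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("the time-frequency map localizes tones with conserved energy", {
  fs <- 50
  x <- sin(2 * pi * 5 * (0:511) / fs)
  tf <- wvd_spectrogram(x, fs)
  expect_s3_class(tf, "tf_map")
  ridge <- tf$freq_axis[apply(tf$matrix, 2, which.max)]
  expect_lt(abs(stats::median(ridge) - 2 * 5 / fs), 0.02)
  expect_lt(abs(sum(tf$matrix) / sum(x^2) - 1), 0.05)
  z <- wvd_spectrogram(numeric(128), fs)
  expect_true(all(z$matrix == 0))
  expect_error(wvd_spectrogram(numeric(32), fs), "short")
})
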