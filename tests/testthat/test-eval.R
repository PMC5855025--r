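test_that("metrics match hand-computed confusion matrices", {
  y <- c("a", "b", "a")
  expect_equal(unname(evaluate_metrics(y, y)), rep(100, 4))

  # TP=9 FP=1 FN=3 TN=7 with positive = "d"
  y_true <- c(rep("d", 12), rep("n", 8))
  y_pred <- c(rep("d", 9), rep("n", 3), "d", rep("n", 7))
  m <- evaluate_metrics(y_true, y_pred, positive = "d")
  expect_equal(unname(m["precision"]), 90)
  expect_equal(unname(m["recall"]), 75)
  expect_equal(unname(m["f_score"]), 2 * 90 * 75 / 165)
  expect_equal(unname(m["accuracy"]), 80)

  # degenerate all-one-class predictions on balanced binary data
  y2 <- rep(c("d", "n"), each = 10)
  m2 <- evaluate_metrics(y2, rep("d", 20), positive = "d")
  expect_equal(unname(m2[c("accuracy", "recall")]), c(50, 100))
  m3 <- evaluate_metrics(y2, rep("n", 20), positive = "d")
  expect_equal(unname(m3[c("accuracy", "recall")]), c(50, 0))

  expect_error(evaluate_metrics(character(0), character(0)), "non-empty")
  expect_error(evaluate_metrics(y, y[1:2]), "equal length")
})

test_that("fold assignment is stratified, seeded and degrades gracefully", {
  y <- rep(c("a", "b", "c"), each = 30)
  f1 <- make_folds(y, folds = 10, seed = 3)
  f2 <- make_folds(y, folds = 10, seed = 3)
  expect_identical(f1, f2)
  expect_false(identical(f1, make_folds(y, folds = 10, seed = 4)))
  for (k in 1:10) {
    expect_equal(as.vector(table(y[f1 == k])), c(3, 3, 3))
  }
  expect_warning(fr <- make_folds(rep(c("a", "b"), c(40, 6)), folds = 10, seed = 1),
                 "reducing folds")
  expect_equal(max(fr), 6)
})

test_that("cross-validation is perfect on separated clusters and chance on permuted labels", {
  set.seed(21)
  X <- rbind(matrix(rnorm(200, 0), 100), matrix(rnorm(200, 6), 100))
  y <- rep(c("a", "b"), each = 100)
  for (kn in c("linear", "poly2", "rbf")) {
    m <- cross_validate(X, y, svm_spec(kn), folds = 10, seed = 2)
    expect_equal(unname(m["accuracy"]), 100)
  }
  accs <- vapply(1:50, function(s) {
    set.seed(s)
    Xp <- matrix(rnorm(90 * 5), 90, 5)
    yp <- sample(rep(c("a", "b", "c"), 30))
    cross_validate(Xp, yp, svm_spec("poly2"), folds = 10, seed = s)[["accuracy"]]
  }, numeric(1))
  se <- stats::sd(accs) / sqrt(length(accs))
  expect_lt(abs(mean(accs) - 100 / 3), 3 * se + 1e-9)
})

test_that("cross-validation is deterministic given the seed", {
  set.seed(5)
  X <- matrix(rnorm(120 * 4), 120, 4)
  y <- rep(c("a", "b", "c"), 40)
  m1 <- cross_validate(X, y, svm_spec("rbf"), seed = 9)
  m2 <- cross_validate(X, y, svm_spec("rbf"), seed = 9)
  expect_identical(m1, m2)
})

test_that("binary f-score is the harmonic mean of reported precision and recall", {
  set.seed(6)
  X <- rbind(matrix(rnorm(160, 0), 80), matrix(rnorm(160, 1), 80))
  y <- rep(c("normal", "phone"), each = 80)
  m <- cross_validate(X, y, svm_spec("linear"), seed = 3, positive = "phone")
  expect_equal(unname(m["f_score"]),
               2 * m[["precision"]] * m[["recall"]] /
                 (m[["precision"]] + m[["recall"]]),
               tolerance = 1e-9)
})

test_that("standardization fitted on training folds does not leak validation labels", {
  # leakage canary: a feature equal to the label, present only in validation
  # folds (zero in training), must not lift accuracy above chance
  set.seed(8)
  n <- 120
  X <- matrix(rnorm(n * 4), n, 4)
  y <- sample(rep(c("a", "b"), each = n / 2))
  fold_id <- make_folds(y, 10, seed = 1)
  accs <- vapply(1:10, function(k) {
    tr <- fold_id != k
    canary <- ifelse(tr, 0, as.numeric(y == "b"))
    Xc <- cbind(X, canary)
    mu <- colMeans(Xc[tr, ]); sg <- apply(Xc[tr, ], 2, stats::sd); sg[sg == 0] <- 1
    fit <- e1071::svm(sweep(sweep(Xc[tr, ], 2, mu), 2, sg, "/"), factor(y[tr]),
                      kernel = "linear", cost = 1, scale = FALSE)
    pred <- predict(fit, sweep(sweep(Xc[!tr, , drop = FALSE], 2, mu), 2, sg, "/"))
    mean(pred == y[!tr])
  }, numeric(1))
  expect_lt(mean(accs), 0.65)
})

test_that("kernel classifiers beat the linear one on radially structured classes", {
  set.seed(10)
  n <- 150
  r <- c(stats::runif(n / 2, 0, 1), stats::runif(n / 2, 1.6, 2.6))
  th <- stats::runif(n, 0, 2 * pi)
  X <- cbind(r * cos(th), r * sin(th))
  y <- rep(c("inner", "outer"), each = n / 2)
  acc <- vapply(c("linear", "poly2", "rbf"), function(kn) {
    cross_validate(X, y, svm_spec(kn), folds = 10, seed = 2)[["accuracy"]]
  }, numeric(1))
  expect_gt(acc[["poly2"]], acc[["linear"]])
  expect_gt(acc[["rbf"]], acc[["linear"]])
})

test_that("cohort evaluation averages equal the mean of per-subject rows", {
  set.seed(13)
  feats <- do.call(rbind, lapply(1:3, function(s) {
    n <- 60
    df <- as.data.frame(matrix(rnorm(n * 18), n, 18))
    names(df) <- feature_names()
    df$f1_mean <- df$f1_mean + rep(c(0, 1, 2), each = n / 3)
    df$subject_id <- sprintf("S%02d", s)
    df$condition <- rep(c("normal", "phone", "text"), each = n / 3)
    df
  }))
  rep_ <- evaluate_cohort(feats, folds = 5, seed = 2)
  for (kn in unique(rep_$averages$kernel)) {
    sub <- rep_$per_subject[rep_$per_subject$kernel == kn, ]
    expect_equal(rep_$averages$accuracy[rep_$averages$kernel == kn],
                 mean(sub$accuracy))
  }
})

test_that("the full pipeline is reproducible and writes its artifacts", {
  out <- file.path(tempdir(), "pipe_out")
  on.exit(unlink(out, recursive = TRUE), add = TRUE)
  cfg <- synth_config(duration_s = 40)
  r1 <- suppressWarnings(run_pipeline(n_subjects = 2, seed = 5, config = cfg,
                                      folds = 5, out_dir = out))
  r2 <- suppressWarnings(run_pipeline(n_subjects = 2, seed = 5, config = cfg,
                                      folds = 5))
  expect_identical(r1$report_full$averages, r2$report_full$averages)
  expect_identical(r1$selected_subset, r2$selected_subset)
  expect_length(r1$selected_subset, 7)
  expect_true(all(file.exists(file.path(out, c(
    "features.csv", "report.json", "ranking_normal_vs_phone.json",
    "ranking_normal_vs_text.csv")))))
  rep_json <- jsonlite::read_json(file.path(out, "report.json"),
                                  simplifyVector = TRUE)
  expect_equal(rep_json$selected_subset, r1$selected_subset)
  # a rerun writes byte-identical report JSON
  out2 <- file.path(tempdir(), "pipe_out2")
  on.exit(unlink(out2, recursive = TRUE), add = TRUE)
  suppressWarnings(run_pipeline(n_subjects = 2, seed = 5, config = cfg,
                                folds = 5, out_dir = out2))
  expect_identical(readLines(file.path(out, "report.json")),
                   readLines(file.path(out2, "report.json")))
})
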