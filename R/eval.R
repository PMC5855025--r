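#' SVM specification
#'
#' The three classifiers used for identification: linear, quadratic
#' polynomial (d = 2) and radial basis function. Hyperparameters: `C = 1`
#' for all kernels, `gamma = 1 / n_features` on standardized inputs (i.e.
#' `1 / (n_features * variance)`), polynomial `coef0 = 1`.
#'
#' @param kernel `"linear"`, `"poly2"` or `"rbf"`.
#' @param C cost (> 0).
#' @param gamma kernel width; `NULL` means `1 / n_features` at fit time.
#' @param coef0 polynomial offset.
#' @return an `svm_spec` object.
#' @export
svm_spec <- function(kernel = c("linear", "poly2", "rbf"), C = 1,
                     gamma = NULL, coef0 = 1) {
  kernel <- match.arg(kernel)
  stop_if_not(C > 0, "`C` must be positive")
  structure(list(kernel = kernel, C = C, gamma = gamma, coef0 = coef0),
            class = "svm_spec")
}

fit_svm <- function(X, y, spec) {
  gamma <- if (is.null(spec$gamma)) 1 / ncol(X) else spec$gamma
  switch(spec$kernel,
    linear = e1071::svm(X, y, kernel = "linear", cost = spec$C, scale = FALSE),
    poly2 = e1071::svm(X, y, kernel = "polynomial", degree = 2, gamma = gamma,
                       coef0 = spec$coef0, cost = spec$C, scale = FALSE),
    rbf = e1071::svm(X, y, kernel = "radial", gamma = gamma, cost = spec$C,
                     scale = FALSE))
}

#' Classification metrics in percent
#'
#' Accuracy is the fraction correct. Precision and recall are macro-averaged
#' over classes unless a `positive` class is given (binary mode, positive =
#' distracted), in which case they are the positive-class values. The
#' F-score is the harmonic mean `2PR / (P + R)` of the reported precision
#' and recall. Classes never predicted contribute precision 0.
#'
#' @param y_true,y_pred label vectors of equal positive length.
#' @param positive optional positive-class label for binary mode.
#' @return named numeric vector `accuracy, precision, recall, f_score`, each
#'   in 0--100.
#' @examples
#' evaluate_metrics(rep(c("d", "n"), c(12, 8)),
#'                  rep(c("d", "n", "d", "n"), c(9, 3, 1, 7)), positive = "d")
#' @export
evaluate_metrics <- function(y_true, y_pred, positive = NULL) {
  stop_if_not(length(y_true) > 0 && length(y_true) == length(y_pred),
              "labels must be non-empty and equal length")
  y_true <- as.character(y_true)
  y_pred <- as.character(y_pred)
  classes <- if (is.null(positive)) sort(unique(y_true)) else positive
  pr <- vapply(classes, function(cl) {
    tp <- sum(y_true == cl & y_pred == cl)
    fp <- sum(y_true != cl & y_pred == cl)
    fn <- sum(y_true == cl & y_pred != cl)
    c(p = if (tp + fp == 0) 0 else tp / (tp + fp),
      r = if (tp + fn == 0) 0 else tp / (tp + fn))
  }, numeric(2))
  p <- mean(pr["p", ])
  r <- mean(pr["r", ])
  f <- if (p + r == 0) 0 else 2 * p * r / (p + r)
  100 * c(accuracy = mean(y_true == y_pred), precision = p, recall = r,
          f_score = f)
}

#' Stratified fold assignment
#'
#' Shuffles indices within each class and deals them round-robin, so folds
#' are balanced. If the rarest class has fewer samples than `folds`, the
#' fold count is reduced with a warning. `mode = "blocked"` assigns
#' contiguous runs within class instead of shuffling, for an
#' overlap-respecting (more conservative) protocol.
#'
#' @param y label vector.
#' @param folds requested fold count (default 10).
#' @param seed RNG seed for the shuffle.
#' @param mode `"shuffled"` (default) or `"blocked"`.
#' @return integer fold id per sample.
#' @export
make_folds <- function(y, folds = 10, seed = 1, mode = c("shuffled", "blocked")) {
  mode <- match.arg(mode)
  y <- as.character(y)
  minc <- min(table(y))
  if (minc < folds) {
    warning(sprintf("rarest class has %d samples; reducing folds to %d", minc, minc))
    folds <- minc
  }
  stop_if_not(folds >= 2, "need at least 2 folds")
  id <- integer(length(y))
  with_seed(seed, {
    for (cl in unique(y)) {
      idx <- which(y == cl)
      if (mode == "shuffled") idx <- sample(idx)
      id[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  id
}

#' Cross-validated SVM identification for one subject
#'
#' Stratified k-fold cross-validation: per fold, standardization is fitted
#' on the training folds only and applied to the validation fold (no
#' leakage), an SVM is trained and the held-out fold predicted. Metrics are
#' computed per fold and averaged; the F-score is the harmonic mean of the
#' averaged precision and recall. Multiclass problems use libsvm's
#' one-vs-one voting.
#'
#' @param X numeric feature matrix.
#' @param y labels (factor or character).
#' @param spec an [svm_spec()].
#' @param folds fold count (default 10).
#' @param seed fold-assignment seed.
#' @param mode fold mode, see [make_folds()].
#' @param positive optional positive class for binary precision/recall.
#' @return named numeric vector `accuracy, precision, recall, f_score` (%).
#' @export
cross_validate <- function(X, y, spec = svm_spec("poly2"), folds = 10,
                           seed = 1, mode = "shuffled", positive = NULL) {
  X <- as.matrix(X)
  y <- factor(y)
  fold_id <- make_folds(y, folds, seed, mode)
  per_fold <- vapply(sort(unique(fold_id)), function(k) {
    tr <- fold_id != k
    mu <- colMeans(X[tr, , drop = FALSE])
    sg <- apply(X[tr, , drop = FALSE], 2, stats::sd)
    sg[sg == 0] <- 1
    Xtr <- sweep(sweep(X[tr, , drop = FALSE], 2, mu), 2, sg, "/")
    Xva <- sweep(sweep(X[!tr, , drop = FALSE], 2, mu), 2, sg, "/")
    fit <- fit_svm(Xtr, droplevels(y[tr]), spec)
    pred <- stats::predict(fit, Xva)
    evaluate_metrics(y[!tr], pred, positive = positive)
  }, numeric(4))
  out <- rowMeans(per_fold)
  out["f_score"] <- if (out["precision"] + out["recall"] == 0) 0 else
    2 * out["precision"] * out["recall"] / (out["precision"] + out["recall"])
  out
}

#' Per-subject cross-validated evaluation report
#'
#' Runs [cross_validate()] for every subject and kernel on a feature table
#' and collects per-subject metrics plus their across-subject averages.
#'
#' @param features feature data.frame (see [feature_table()]).
#' @param feature_cols character vector of feature columns to use.
#' @param kernels kernels to evaluate (default all three).
#' @param folds,seed,mode CV controls.
#' @return an `eval_report`: `per_subject` (data.frame: subject, kernel,
#'   accuracy, precision, recall, f_score), `averages` (by kernel),
#'   `feature_cols`, `fold_seed`.
#' @export
evaluate_cohort <- function(features, feature_cols = feature_names(),
                            kernels = c("linear", "poly2", "rbf"),
                            folds = 10, seed = 1, mode = "shuffled") {
  subjects <- unique(features$subject_id)
  rows <- list()
  for (s in subjects) {
    sub <- features[features$subject_id == s, ]
    X <- as.matrix(sub[, feature_cols])
    for (kn in kernels) {
      m <- cross_validate(X, sub$condition, svm_spec(kn), folds = folds,
                          seed = seed, mode = mode)
      rows[[length(rows) + 1L]] <- data.frame(
        subject = s, kernel = kn, accuracy = m[["accuracy"]],
        precision = m[["precision"]], recall = m[["recall"]],
        f_score = m[["f_score"]])
    }
  }
  per_subject <- do.call(rbind, rows)
  averages <- do.call(rbind, lapply(split(per_subject, per_subject$kernel),
    function(d) data.frame(kernel = d$kernel[1], accuracy = mean(d$accuracy),
                           precision = mean(d$precision),
                           recall = mean(d$recall),
                           f_score = mean(d$f_score))))
  rownames(averages) <- NULL
  structure(list(per_subject = per_subject, averages = averages,
                 feature_cols = feature_cols, fold_seed = seed),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %d subjects, %d features, fold seed %s\n",
              length(unique(x$per_subject$subject)), length(x$feature_cols),
              format(x$fold_seed)))
  print(x$averages, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Run the full distraction-identification pipeline
#'
#' Orchestrates every stage on a synthetic cohort: simulate -> preprocess
#' (low-pass + resample to the working rate) -> continuous decomposition ->
#' windowed feature extraction -> SVM-RFE consensus selection (both binary
#' scenarios) -> kernel-SVM 10-fold CV on the full 18-feature space and on
#' the reduced consensus subset.
#'
#' @param n_subjects cohort size (default 10).
#' @param seed master seed (drives simulation and fold assignment).
#' @param config a [synth_config()]; its seed is overridden by `seed`.
#' @param fs_out working rate (Hz, default 50).
#' @param peak_threshold pipeline peak-scan threshold (see [feature_table()]).
#' @param k consensus subset size (default 7).
#' @param kernels kernels to evaluate.
#' @param folds CV folds.
#' @param mode fold mode, see [make_folds()].
#' @param out_dir optional directory: when given, recordings, decompositions,
#'   the feature table, rankings and the report are written there.
#' @return a `pipeline_result`: `features`, `ranking_phone`, `ranking_text`,
#'   `selected_subset`, `report_full`, `report_reduced`.
#' @export
run_pipeline <- function(n_subjects = 10, seed = 1, config = synth_config(),
                         fs_out = 50, peak_threshold = 0.004, k = 7,
                         kernels = c("linear", "poly2", "rbf"), folds = 10,
                         mode = "shuffled", out_dir = NULL) {
  config$seed <- as.integer(seed)
  cohort <- generate_cohort(n_subjects, config)
  params <- irf_params(config$tau1, config$tau2)
  feats <- do.call(rbind, lapply(cohort, function(e) {
    dec <- decompose(preprocess(e$recording, fs_out = fs_out), params)
    feature_table(dec, peak_threshold = peak_threshold)
  }))
  ranking_phone <- rank_cohort(feats, "normal_vs_phone", k = k)
  ranking_text <- rank_cohort(feats, "normal_vs_text", k = k)
  selected <- ranking_phone$selected_subset
  report_full <- evaluate_cohort(feats, feature_names(), kernels, folds,
                                 seed, mode)
  report_reduced <- evaluate_cohort(feats, feature_names()[selected], kernels,
                                    folds, seed, mode)
  res <- structure(
    list(features = feats, ranking_phone = ranking_phone,
         ranking_text = ranking_text, selected_subset = selected,
         report_full = report_full, report_reduced = report_reduced,
         seed = seed),
    class = "pipeline_result")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_cohort_csv(cohort, file.path(out_dir, "recordings"))
    utils::write.csv(feats, file.path(out_dir, "features.csv"),
                     row.names = FALSE)
    write_ranking(ranking_phone,
                  file.path(out_dir, "ranking_normal_vs_phone.json"),
                  file.path(out_dir, "ranking_normal_vs_phone.csv"))
    write_ranking(ranking_text,
                  file.path(out_dir, "ranking_normal_vs_text.json"),
                  file.path(out_dir, "ranking_normal_vs_text.csv"))
    jsonlite::write_json(
      list(seed = seed, selected_subset = selected,
           full18 = list(per_subject = res$report_full$per_subject,
                         averages = res$report_full$averages),
           reduced = list(per_subject = res$report_reduced$per_subject,
                          averages = res$report_reduced$averages)),
      file.path(out_dir, "report.json"), auto_unbox = TRUE, pretty = TRUE,
      digits = NA)
  }
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> seed %s, %d windows\n", format(x$seed),
              nrow(x$features)))
  cat("  selected subset:", x$selected_subset, "\n")
  cat("  full 18-feature averages:\n")
  print(x$report_full$averages, row.names = FALSE, digits = 4)
  cat(sprintf("  reduced %d-feature averages:\n", length(x$selected_subset)))
  print(x$report_reduced$averages, row.names = FALSE, digits = 4)
  invisible(x)
}
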