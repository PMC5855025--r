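#' Rank features by linear SVM recursive feature elimination
#'
#' Backward elimination: a linear SVM is trained on the remaining features,
#' the weight vector `w = sum_j alpha_j y_j x_j` is read off the support
#' vectors, and the feature with the smallest squared weight `c_i = w_i^2`
#' is removed; repeat until one feature remains. One feature is removed per
#' iteration. Features are standardized before each fit (the squared-weight
#' criterion presumes comparable scales); constant columns get weight zero,
#' so among tied minima a degenerate feature is eliminated first, and
#' remaining ties eliminate the larger column index.
#'
#' @param X numeric matrix (windows x features).
#' @param y binary labels (two distinct values).
#' @param C linear SVM cost (default 1).
#' @return integer vector: column indices of `X`, best-ranked first (a
#'   permutation of `1:ncol(X)`).
#' @examples
#' set.seed(1)
#' X <- cbind(sig = rep(0:1, each = 20) + rnorm(40, sd = 0.1),
#'            noise = rnorm(40))
#' svm_rfe_rank(X, rep(c("a", "b"), each = 20))  # c(1, 2)
#' @export
svm_rfe_rank <- function(X, y, C = 1) {
  X <- as.matrix(X)
  y <- factor(y)
  stop_if_not(nlevels(y) == 2, "SVM-RFE is a binary technique: need exactly 2 classes")
  stop_if_not(nrow(X) == length(y), "X and y sizes differ")
  remaining <- seq_len(ncol(X))
  eliminated <- integer(0)
  while (length(remaining) > 1) {
    Xs <- scale(X[, remaining, drop = FALSE])
    const <- !is.finite(colSums(Xs)) | apply(X[, remaining, drop = FALSE], 2,
                                             function(v) stats::sd(v) == 0)
    Xs[, const] <- 0
    fit <- e1071::svm(Xs, y, kernel = "linear", cost = C, scale = FALSE)
    w <- as.numeric(crossprod(fit$coefs, fit$SV))
    crit <- w^2
    crit[const] <- -Inf                     # degenerate features go first
    worst <- max(which(crit == min(crit)))  # ties: drop the larger index
    eliminated <- c(eliminated, remaining[worst])
    remaining <- remaining[-worst]
  }
  rev(c(eliminated, remaining))
}

#' Per-subject SVM-RFE rankings for a binary scenario
#'
#' Restricts the feature table to one subject and the two conditions of the
#' scenario, ranks the 18 features by [svm_rfe_rank()], and repeats per
#' subject -- mirroring the per-driver rank tables of the identification
#' protocol. Subjects missing one of the two classes are skipped with a
#' warning.
#'
#' @param features feature data.frame from [feature_table()] (stacked over a
#'   cohort): 18 feature columns plus `subject_id`, `condition`.
#' @param scenario `"normal_vs_phone"` or `"normal_vs_text"`.
#' @param k consensus subset size (default 7).
#' @param C linear SVM cost.
#' @return a `ranking_result`: `scenario`, `per_subject_ranks` (subjects x 18
#'   matrix, rank 1 first), `consensus_row`, `selected_subset` (sorted).
#' @export
rank_cohort <- function(features, scenario = c("normal_vs_phone", "normal_vs_text"),
                        k = 7, C = 1) {
  scenario <- match.arg(scenario)
  pair <- c("normal", strsplit(scenario, "_vs_")[[1]][2])
  fcols <- feature_names()
  stop_if_not(all(fcols %in% names(features)), "feature columns missing")
  subjects <- unique(features$subject_id)
  ranks <- list()
  for (s in subjects) {
    sub <- features[features$subject_id == s & features$condition %in% pair, ]
    if (length(unique(sub$condition)) < 2) {
      warning(sprintf("subject %s lacks both classes for %s; skipped", s, scenario))
      next
    }
    ranks[[s]] <- svm_rfe_rank(as.matrix(sub[, fcols]), sub$condition, C = C)
  }
  stop_if_not(length(ranks) >= 1, "no subject had both classes")
  per_subject <- do.call(rbind, ranks)
  cons <- consensus_select(per_subject, k = k)
  structure(list(scenario = scenario, per_subject_ranks = per_subject,
                 consensus_row = cons$consensus_row,
                 selected_subset = cons$selected_subset),
            class = "ranking_result")
}

#' @export
print.ranking_result <- function(x, ...) {
  cat(sprintf("<ranking_result> %s: %d subjects\n", x$scenario,
              nrow(x$per_subject_ranks)))
  cat("  consensus row:", x$consensus_row, "\n")
  cat("  selected subset:", x$selected_subset, "\n")
  invisible(x)
}

#' Cross-subject consensus feature selection
#'
#' For each rank position the modal feature index across subjects is taken
#' (ties broken toward the smaller index); the selected subset is the first
#' `k` distinct features encountered scanning the consensus row left to
#' right. This is the rule that yields a unified subset from per-subject
#' rank lists.
#'
#' @param per_subject_ranks matrix of rankings (subjects x positions, rank 1
#'   in column 1); each row a permutation of the feature indices.
#' @param k subset size (default 7).
#' @return list with `consensus_row` (modal feature per position) and
#'   `selected_subset` (sorted integer vector of length `k`).
#' @export
consensus_select <- function(per_subject_ranks, k = 7) {
  m <- as.matrix(per_subject_ranks)
  stop_if_not(nrow(m) >= 1, "need at least one ranking")
  consensus_row <- apply(m, 2, function(col) {
    tab <- table(col)
    cand <- as.integer(names(tab)[tab == max(tab)])
    min(cand)
  })
  distinct <- unique(consensus_row)
  stop_if_not(k <= length(distinct),
              sprintf("k = %d exceeds the %d distinct consensus features", k,
                      length(distinct)))
  list(consensus_row = as.integer(consensus_row),
       selected_subset = sort(distinct[seq_len(k)]))
}

#' Published per-subject rank tables (worked example)
#'
#' Per-subject SVM-RFE rank lists reported by a 10-driver wearable
#' distraction study, for the two binary scenarios (normal vs. phone and
#' normal vs. text). They serve as the worked example for
#' [consensus_select()]: the consensus rule recovers the study's unified
#' 7-feature subset \{6, 9, 13, 14, 15, 17, 18\} from either table.
#'
#' @param scenario which table to load.
#' @return 10 x 18 integer matrix, one row per subject, rank 1 in column 1.
#' @examples
#' consensus_select(published_rank_table("normal_vs_phone"))$selected_subset
#' @export
published_rank_table <- function(scenario = c("normal_vs_phone", "normal_vs_text")) {
  scenario <- match.arg(scenario)
  path <- system.file("extdata", paste0("rfe_ranks_", scenario, ".csv"),
                      package = "gsrdistract", mustWork = TRUE)
  as.matrix(utils::read.csv(path, row.names = 1))
}

#' Write a ranking result to disk
#'
#' JSON with scenario, per-subject rank lists, consensus row and selected
#' subset, plus a CSV laid out like the published rank tables (one row per
#' subject, a consensus row at the bottom).
#'
#' @param res a [rank_cohort()] result.
#' @param path_json,path_csv output paths (either may be `NULL` to skip).
#' @return `invisible(NULL)`.
#' @export
write_ranking <- function(res, path_json = NULL, path_csv = NULL) {
  if (!is.null(path_json)) {
    jsonlite::write_json(
      list(scenario = res$scenario,
           per_subject_ranks = apply(res$per_subject_ranks, 1, identity,
                                     simplify = FALSE),
           consensus_row = res$consensus_row,
           selected_subset = res$selected_subset),
      path_json, auto_unbox = TRUE, pretty = TRUE)
  }
  if (!is.null(path_csv)) {
    out <- rbind(res$per_subject_ranks, consensus = res$consensus_row)
    utils::write.csv(out, path_csv)
  }
  invisible(NULL)
}
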