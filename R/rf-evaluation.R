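#' Random-Forest leave-one-out cross-validation
#'
#' Trains one forest per leave-one-out fold (N folds for N samples), records
#' the held-out sample's predicted cancer probability, and averages each
#' peptide's mean-decrease-Gini importance across folds for a stable
#' feature ranking. Predicted probabilities are pooled across folds to
#' build the ROC curve and confusion summary.
#'
#' Forest hyperparameters beyond the tree count follow the common
#' classification defaults (sqrt(p) candidate features per split, unlimited
#' depth, bootstrap sampling). Each fold is seeded deterministically from
#' `seed` and the fold index, so the whole result is reproducible.
#'
#' @param table completed, collapsed [peptide_table] (features = peptides).
#' @param labels [group_labels]; every training fold must contain both
#'   classes (guaranteed when each class has at least 2 samples).
#' @param n_trees trees per forest (default 100).
#' @param seed master RNG seed.
#' @param probability_threshold cancer-call cutoff on the predicted
#'   probability (default 0.5; a probability equal to the threshold is
#'   called cancer).
#' @return list of class `loocv_rf`:
#'   `predictions` (data.frame `sample_id`, `probability`, `predicted`,
#'   `truth`, `category` in TP/TN/FP/FN),
#'   `accuracy`, `sensitivity`, `specificity`, `auc`,
#'   `roc` (data.frame of ROC points),
#'   `importance` (data.frame `peptide`, `mean_gini`, `rank`, sorted by
#'   decreasing importance).
#' @export
loocv_rf <- function(table, labels, n_trees = 100, seed = 1L,
                     probability_threshold = 0.5) {
  stopifnot(inherits(table, "peptide_table"))
  if (anyNA(table$intensity))
    stop("loocv_rf requires a completed (imputed) table")
  if (n_trees < 1) stop("n_trees must be at least 1")
  y <- check_labels(table, labels)
  n <- length(y)
  if (n < 3) stop("need at least 3 samples for LOOCV")
  if (min(sum(y == 0), sum(y == 1)) < 2)
    stop("each class needs at least 2 samples so every fold sees both classes")
  x <- t(table$intensity)   # samples x features
  colnames(x) <- table$meta$peptide
  yf <- factor(y, levels = c(0, 1))

  prob <- numeric(n)
  gini <- matrix(0, ncol(x), n, dimnames = list(colnames(x), NULL))
  for (i in seq_len(n)) {
    set.seed((seed + 7919L * i) %% 2147483647L)
    fit <- randomForest::randomForest(x[-i, , drop = FALSE], yf[-i],
                                      ntree = n_trees)
    prob[i] <- stats::predict(fit, x[i, , drop = FALSE],
                              type = "prob")[, "1"]
    gini[, i] <- fit$importance[, "MeanDecreaseGini"]
  }
  conf <- confusion_report(prob, y, threshold = probability_threshold)
  conf$predictions$sample_id <- colnames(table$intensity)
  conf$predictions <- conf$predictions[, c("sample_id", "probability",
                                           "predicted", "truth", "category")]
  roc <- roc_auc(prob, y)
  mg <- rowMeans(gini)
  imp <- data.frame(peptide = names(mg), mean_gini = unname(mg),
                    stringsAsFactors = FALSE)
  imp <- imp[order(-imp$mean_gini), ]
  imp$rank <- seq_len(nrow(imp))
  rownames(imp) <- NULL
  structure(list(predictions = conf$predictions,
                 accuracy = conf$accuracy,
                 sensitivity = conf$sensitivity,
                 specificity = conf$specificity,
                 auc = roc$auc, roc = roc$points, importance = imp,
                 config = list(n_trees = n_trees, seed = seed,
                               probability_threshold = probability_threshold)),
            class = "loocv_rf")
}

#' @export
print.loocv_rf <- function(x, ...) {
  cat(sprintf("LOOCV random forest: %d samples, %d features, %d trees/fold\n",
              nrow(x$predictions), nrow(x$importance), x$config$n_trees))
  cat(sprintf("  accuracy %.3f  sensitivity %.3f  specificity %.3f  AUC %.3f\n",
              x$accuracy, x$sensitivity, x$specificity, x$auc))
  invisible(x)
}

#' ROC curve and AUC by threshold sweep
#'
#' Sweeps the distinct predicted probabilities as thresholds, computes the
#' (FPR, TPR) points, and integrates the curve with the trapezoid rule.
#' The resulting AUC equals the rank statistic: the probability that a
#' random cancer sample outscores a random control, ties counted half.
#'
#' @param probabilities per-sample predicted cancer probabilities.
#' @param labels binary labels (1 = cancer).
#' @return list with `points` (data.frame `threshold`, `fpr`, `tpr`) and
#'   `auc`.
#' @export
roc_auc <- function(probabilities, labels) {
  y <- as.integer(unclass(labels))
  if (length(y) != length(probabilities)) stop("length mismatch")
  if (sum(y) == 0 || sum(y) == length(y))
    stop("both classes must be present")
  thr <- c(Inf, sort(unique(probabilities), decreasing = TRUE))
  tpr <- vapply(thr, function(t) mean(probabilities[y == 1] >= t), 0)
  fpr <- vapply(thr, function(t) mean(probabilities[y == 0] >= t), 0)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + tpr[-1]) / 2)
  list(points = data.frame(threshold = thr, fpr = fpr, tpr = tpr),
       auc = auc)
}

#' Per-sample confusion categories and summary metrics
#'
#' Calls a sample cancer when its predicted probability is greater than or
#' equal to `threshold`, assigns TP/TN/FP/FN against the true labels, and
#' summarizes accuracy, sensitivity = TP/(TP+FN) and specificity =
#' TN/(TN+FP).
#'
#' @inheritParams roc_auc
#' @param threshold cancer-call cutoff in (0, 1).
#' @return list with `predictions` (data.frame `probability`, `predicted`,
#'   `truth`, `category`), `counts` (named TP/TN/FP/FN), `accuracy`,
#'   `sensitivity`, `specificity`.
#' @export
confusion_report <- function(probabilities, labels, threshold = 0.5) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  y <- as.integer(unclass(labels))
  pred <- as.integer(probabilities >= threshold)
  category <- ifelse(y == 1, ifelse(pred == 1, "TP", "FN"),
                     ifelse(pred == 1, "FP", "TN"))
  counts <- vapply(c("TP", "TN", "FP", "FN"),
                   function(k) sum(category == k), 0L)
  list(predictions = data.frame(probability = probabilities,
                                predicted = pred, truth = y,
                                category = category,
                                stringsAsFactors = FALSE),
       counts = counts,
       accuracy = (counts[["TP"]] + counts[["TN"]]) / length(y),
       sensitivity = counts[["TP"]] / (counts[["TP"]] + counts[["FN"]]),
       specificity = counts[["TN"]] / (counts[["TN"]] + counts[["FP"]]))
}

#' Concordance between two feature rankings
#'
#' Descriptive comparison of two importance score vectors over the same
#' peptide set: the size of the overlap between their top-k lists and the
#' Spearman rank correlation over the full set.
#'
#' @param score_a,score_b named numeric score vectors (higher = more
#'   important) over the same names.
#' @param k top-list size.
#' @return list with `k`, `overlap`, `top_a`, `top_b`, `spearman`.
#' @export
rank_concordance <- function(score_a, score_b, k) {
  if (is.null(names(score_a)) || is.null(names(score_b)))
    stop("score vectors must be named")
  if (!setequal(names(score_a), names(score_b)))
    stop("rankings cover different peptide sets")
  if (k > length(score_a)) stop("k exceeds the set size")
  score_b <- score_b[names(score_a)]
  top_a <- names(sort(score_a, decreasing = TRUE))[seq_len(k)]
  top_b <- names(sort(score_b, decreasing = TRUE))[seq_len(k)]
  list(k = k,
       overlap = length(intersect(top_a, top_b)),
       top_a = top_a, top_b = top_b,
       spearman = stats::cor(score_a, score_b, method = "spearman"))
}
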