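#' Per-class confusion counts
#'
#' For each class `c` of the strong/moderate/weak alphabet: `TP_c`
#' (true = c and predicted = c), `FP_c` (true != c, predicted = c) and
#' `FN_c` (true = c, predicted != c).
#'
#' @param y_true,y_pred Label vectors of equal length, values in
#'   `fitness_levels()`.
#' @return A `confusion_counts` data frame with columns `class`, `tp`,
#'   `fp`, `fn`.
#' @export
confusion_counts <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred))
    stop("`y_true` and `y_pred` must have equal length", call. = FALSE)
  lv <- fitness_levels()
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  bad <- setdiff(unique(c(y_true, y_pred)), lv)
  if (length(bad))
    stop("labels outside {strong, moderate, weak}: ",
         paste(bad, collapse = ", "), call. = FALSE)
  counts <- lapply(lv, function(cl) {
    data.frame(class = cl,
               tp = sum(y_true == cl & y_pred == cl),
               fp = sum(y_true != cl & y_pred == cl),
               fn = sum(y_true == cl & y_pred != cl))
  })
  structure(do.call(rbind, counts), class = c("confusion_counts",
                                              "data.frame"))
}

#' Precision, recall and F1 from confusion counts
#'
#' Per class: `precision = TP / (TP + FP)`, `recall = TP / (TP + FN)`,
#' `f1 = 2 P R / (P + R)`; any 0/0 is defined as 0. Macro values are
#' unweighted means over the three classes.
#'
#' @param counts A [confusion_counts()] data frame.
#' @return A `metrics_report` list with a per-class data frame
#'   (`by_class`) and `macro_precision`, `macro_recall`, `macro_f1`.
#' @export
precision_recall_f1 <- function(counts) {
  safe_div <- function(num, den) ifelse(den == 0, 0, num / den)
  p <- safe_div(counts$tp, counts$tp + counts$fp)
  r <- safe_div(counts$tp, counts$tp + counts$fn)
  f1 <- safe_div(2 * p * r, p + r)
  structure(
    list(by_class = data.frame(class = counts$class, precision = p,
                               recall = r, f1 = f1),
         macro_precision = mean(p), macro_recall = mean(r),
         macro_f1 = mean(f1)),
    class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("Per-class metrics:\n")
  print(format(x$by_class, digits = 4), row.names = FALSE)
  cat(sprintf("Macro: precision %.4f, recall %.4f, F1 %.4f\n",
              x$macro_precision, x$macro_recall, x$macro_f1))
  invisible(x)
}

#' Unweighted macro average
#'
#' The averaging rule used throughout the evaluation: the plain
#' unweighted mean, applied to per-class metrics within a report and to
#' per-test F1 values within a classifier's row of the evaluation table.
#'
#' @param x A numeric vector.
#' @return Its mean.
#' @export
macro_average <- function(x) mean(as.numeric(x))

# Stratified fold ids: within each class, a seeded shuffle then
# round-robin assignment, so fold class proportions match the data.
stratified_folds <- function(y, k_folds, seed) {
  rng <- local_rng(seed)
  on.exit(rng())
  fold <- integer(length(y))
  for (cl in unique(as.character(y))) {
    idx <- which(as.character(y) == cl)
    if (length(idx) < k_folds)
      stop("class `", cl, "` has fewer than ", k_folds,
           " members; cannot stratify", call. = FALSE)
    fold[sample(idx)] <- rep_len(seq_len(k_folds), length(idx))
  }
  fold
}

#' Stratified k-fold cross-validation of one classifier on one test
#'
#' Splits the cohort into `k_folds` class-stratified folds with a seeded
#' shuffle, trains on each training portion and evaluates on the held-out
#' fold, then averages the per-fold metrics (unweighted mean of the fold
#' macro-F1 and of each per-class F1).
#'
#' @inheritParams train_naive_bayes
#' @param method `"naive_bayes"`, `"knn"` or `"lda"`.
#' @param k_folds Number of folds (default 4).
#' @param seed Integer seed for the fold shuffle.
#' @param k Neighbour count for the KNN learner.
#' @return A `cv_report` list: `macro_f1`, `per_class_f1` (named numeric),
#'   `macro_precision`, `macro_recall`, `folds` (per-fold macro-F1),
#'   `method`, `test`.
#' @export
kfold_cv <- function(data, test, method, k_folds = 4L, seed = 1L, k = 3L) {
  y <- test_labels(data, test)
  fold <- stratified_folds(y, k_folds, seed)
  per_fold <- lapply(seq_len(k_folds), function(f) {
    train <- data[fold != f, , drop = FALSE]
    heldout <- data[fold == f, , drop = FALSE]
    model <- fit_classifier(train, test, method, k = k)
    pred <- predict(model, heldout)
    precision_recall_f1(confusion_counts(test_labels(heldout, test), pred))
  })
  f1_mat <- vapply(per_fold, function(m) m$by_class$f1, numeric(3L))
  structure(
    list(macro_f1 = mean(vapply(per_fold, `[[`, numeric(1), "macro_f1")),
         per_class_f1 = stats::setNames(rowMeans(f1_mat), fitness_levels()),
         macro_precision = mean(vapply(per_fold, `[[`, numeric(1),
                                       "macro_precision")),
         macro_recall = mean(vapply(per_fold, `[[`, numeric(1),
                                    "macro_recall")),
         folds = vapply(per_fold, `[[`, numeric(1), "macro_f1"),
         method = method, test = test),
    class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("%d-fold CV of %s on the %s test: macro-F1 %.4f\n",
              length(x$folds), x$method, x$test, x$macro_f1))
  invisible(x)
}

#' Cross-validate all classifiers on all four fitness tests
#'
#' Runs [kfold_cv()] for naive Bayes, KNN and LDA on each of the four
#' test labels, producing the 3 x 4 table of average F1 values, each
#' classifier's macro average over the four tests, and the best
#' classifier by that average.
#'
#' @inheritParams kfold_cv
#' @return A `fitness_evaluation` with elements `f1_table` (3 x 4
#'   matrix, classifiers x tests), `classifier_average` (named numeric),
#'   and `best` (name of the argmax classifier).
#' @export
evaluate_all <- function(data, k_folds = 4L, seed = 1L, k = 3L) {
  methods <- classifier_methods()
  tests <- fitness_tests()
  tab <- matrix(NA_real_, length(methods), length(tests),
                dimnames = list(methods, tests))
  for (m in methods)
    for (tst in tests)
      tab[m, tst] <- kfold_cv(data, tst, m, k_folds = k_folds, seed = seed,
                              k = k)$macro_f1
  avg <- apply(tab, 1, macro_average)
  structure(list(f1_table = tab, classifier_average = avg,
                 best = names(avg)[which.max(avg)],
                 k_folds = k_folds, seed = seed),
            class = "fitness_evaluation")
}

#' @export
print.fitness_evaluation <- function(x, ...) {
  cat(sprintf("Average F1 over %d-fold cross-validation:\n", x$k_folds))
  print(round(x$f1_table, 3))
  cat("Classifier macro averages: ",
      paste(sprintf("%s %.3f", names(x$classifier_average),
                    x$classifier_average), collapse = ", "), "\n", sep = "")
  cat("Best classifier:", x$best, "\n")
  invisible(x)
}
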