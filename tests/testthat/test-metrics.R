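test_that("confusion counts enumerate TP/FP/FN per class", {
  cc <- confusion_counts(c("strong", "strong", "moderate"),
                         c("strong", "moderate", "moderate"))
  get <- function(cl, col) cc[cc$class == cl, col]
  expect_identical(get("strong", "tp"), 1L)
  expect_identical(get("strong", "fn"), 1L)
  expect_identical(get("moderate", "fp"), 1L)
  expect_identical(get("moderate", "tp"), 1L)
  expect_identical(sum(cc$tp) + sum(cc$fn), 3L)

  perfect <- confusion_counts(rep(fitness_levels(), 2),
                              rep(fitness_levels(), 2))
  expect_true(all(perfect$fp == 0L) && all(perfect$fn == 0L))

  expect_error(confusion_counts("strong", "excellent"), "outside")
  expect_error(confusion_counts(c("strong", "weak"), "weak"), "equal length")
})

test_that("precision/recall/F1 follow their formulas with the 0/0 convention", {
  rep1 <- precision_recall_f1(
    data.frame(class = "strong", tp = 10L, fp = 0L, fn = 0L))
  expect_equal(rep1$by_class$precision[1], 1)
  expect_equal(rep1$by_class$recall[1], 1)
  expect_equal(rep1$by_class$f1[1], 1)

  rep2 <- precision_recall_f1(
    data.frame(class = "weak", tp = 8L, fp = 2L, fn = 4L))
  expect_equal(rep2$by_class$precision[1], 0.8)
  expect_equal(rep2$by_class$recall[1], 8 / 12, tolerance = 1e-12)
  expect_equal(rep2$by_class$f1[1], 2 * 0.8 * (2 / 3) / (0.8 + 2 / 3),
               tolerance = 1e-12)

  rep3 <- precision_recall_f1(
    data.frame(class = "moderate", tp = 0L, fp = 0L, fn = 5L))
  expect_equal(rep3$by_class$f1[1], 0)
})

test_that("metrics match exhaustive enumeration over all prediction patterns", {
  y_true <- c("strong", "strong", "moderate", "weak")
  lv <- fitness_levels()
  patterns <- expand.grid(lv, lv, lv, lv, stringsAsFactors = FALSE)
  for (r in seq_len(nrow(patterns))) {          # all 3^4 = 81 patterns
    y_pred <- unlist(patterns[r, ], use.names = FALSE)
    rep <- precision_recall_f1(confusion_counts(y_true, y_pred))
    # independent oracle: direct pair counting per class
    for (cl in lv) {
      tp <- sum(y_true == cl & y_pred == cl)
      fp <- sum(y_true != cl & y_pred == cl)
      fn <- sum(y_true == cl & y_pred != cl)
      p <- if (tp + fp == 0) 0 else tp / (tp + fp)
      rc <- if (tp + fn == 0) 0 else tp / (tp + fn)
      f1 <- if (p + rc == 0) 0 else 2 * p * rc / (p + rc)
      row <- rep$by_class[rep$by_class$class == cl, ]
      expect_equal(row$precision, p)
      expect_equal(row$recall, rc)
      expect_equal(row$f1, f1)
      # identities: harmonic mean, range, F1 = 1 iff no errors
      expect_true(row$f1 >= 0 && row$f1 <= 1)
      if (p + rc > 0) expect_equal(row$f1, 2 / (1 / max(p, 1e-300) + 1 / max(rc, 1e-300)),
                                   tolerance = 1e-9)
      expect_identical(row$f1 == 1, fp == 0L && fn == 0L)
    }
    expect_equal(rep$macro_f1, mean(rep$by_class$f1))
  }
})

test_that("stratified k-fold cross-validation is seeded and stratified", {
  coh <- generate_cohort(cohort_spec(n_subjects = 120, seed = 2))
  a <- kfold_cv(coh, "flexibility", "naive_bayes", seed = 10)
  b <- kfold_cv(coh, "flexibility", "naive_bayes", seed = 10)
  expect_identical(a, b)
  c <- kfold_cv(coh, "flexibility", "naive_bayes", seed = 11)
  expect_false(identical(a$folds, c$folds))
  expect_length(a$folds, 4L)
  expect_named(a$per_class_f1, fitness_levels())

  tiny <- toy_dataset(c(rep("strong", 8), rep("weak", 3)))
  expect_error(kfold_cv(tiny, "balance", "lda"), "stratify")
})

test_that("shuffled labels drop cross-validated macro-F1 to chance", {
  coh <- generate_cohort(cohort_spec(n_subjects = 850, seed = 31))
  set.seed(99)
  coh$label_balance <- sample(coh$label_balance)
  cv <- kfold_cv(coh, "balance", "naive_bayes", seed = 7)
  expect_lt(abs(cv$macro_f1 - 1 / 3), 0.08)
})

test_that("evaluate_all builds the 3 x 4 table and selects the best learner", {
  coh <- generate_cohort(cohort_spec(n_subjects = 160, seed = 4))
  ev <- evaluate_all(coh, seed = 3)
  expect_identical(dim(ev$f1_table), c(3L, 4L))
  expect_identical(sum(!is.na(ev$f1_table)), 12L)
  expect_identical(colnames(ev$f1_table), fitness_tests())
  expect_equal(ev$classifier_average,
               apply(ev$f1_table, 1, mean))
  expect_true(ev$best %in% rownames(ev$f1_table))
  expect_identical(ev$best,
                   names(which.max(ev$classifier_average)))
})

test_that("Gaussian class structure favours naive Bayes over KNN", {
  diffs <- vapply(1:20, function(s) {
    coh <- generate_cohort(cohort_spec(n_subjects = 85, seed = 400 + s))
    nb <- mean(vapply(fitness_tests(), function(tst)
      kfold_cv(coh, tst, "naive_bayes", seed = s)$macro_f1, numeric(1)))
    kn <- mean(vapply(fitness_tests(), function(tst)
      kfold_cv(coh, tst, "knn", seed = s)$macro_f1, numeric(1)))
    nb - kn
  }, numeric(1))
  expect_gte(mean(diffs), 0)
})
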