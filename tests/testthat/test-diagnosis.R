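test_that("preprocess encodes records in the fixed instance order", {
  inst <- preprocess(worked_record())
  expect_equal(unname(inst), c(0, 25, 50, 25, 29.4, 501, 12.2, 5.86))
  expect_identical(names(inst), fitness_features())

  male <- worked_record(); male$gender <- 1
  expect_equal(unname(preprocess(male))[1], 1)

  # distinct records map to distinct instances
  other <- worked_record(); other$balance <- 5.87
  expect_false(identical(preprocess(worked_record()), preprocess(other)))

  expect_error(preprocess(worked_record()[-3]), "weight")
  bad <- worked_record(); bad$age <- NaN
  expect_error(preprocess(bad), "age")
  bad$age <- "old"
  expect_error(preprocess(bad), "age")
  bad <- worked_record(); bad$gender <- 2
  expect_error(preprocess(bad), "gender")
})

test_that("naive Bayes separates well-spaced classes and estimates priors", {
  d <- toy_dataset(rep(c("strong", "weak"), each = 10), sep = 10,
                   noise = 0.1)
  m <- train_naive_bayes(d, "flexibility")
  expect_equal(as.character(predict(m, d)), d$label_flexibility)
  expect_equal(vapply(m$stats, `[[`, numeric(1), "prior"),
               c(strong = 0.5, weak = 0.5))

  expect_error(train_naive_bayes(toy_dataset(rep("weak", 6)), "balance"),
               "two classes")
})

test_that("naive Bayes posteriors match direct Bayes-rule arithmetic", {
  # two one-per-class points; floored variance makes both class
  # likelihoods proper, and a query at a class mean must take posterior
  # mass above that class's prior share
  d <- toy_dataset(c("strong", "weak"), sep = 6, noise = 0)
  m <- train_naive_bayes(d, "grip_strength")
  x <- feature_matrix(d)
  post <- function(q) {
    lik <- vapply(m$classes, function(cl) {
      s <- m$stats[[cl]]
      s$prior * prod(stats::dnorm(q, s$mean, sqrt(s$var)))
    }, numeric(1))
    lik / sum(lik)
  }
  expect_gt(post(x[1, ])[["strong"]], m$stats$strong$prior)
  expect_identical(as.character(predict(m, x[1, , drop = FALSE])), "strong")
  expect_identical(as.character(predict(m, x[2, , drop = FALSE])), "weak")
})

test_that("KNN votes over z-scored Euclidean neighbours with nearest tie-break", {
  d <- toy_dataset(rep(c("strong", "moderate", "weak"), times = 4),
                   sep = 8, noise = 0.2)
  m1 <- train_knn(d, "flexibility", k = 1)
  expect_equal(as.character(predict(m1, d)), d$label_flexibility)

  # balanced two-class data with k = n: vote ties, nearest neighbour wins
  d2 <- toy_dataset(rep(c("strong", "weak"), each = 3), sep = 6, noise = 0.1)
  m2 <- train_knn(d2, "balance", k = 6)
  pred <- as.character(predict(m2, d2))
  expect_equal(pred, d2$label_balance)

  # three points on a line: query nearer the two 'strong' points
  d3 <- toy_dataset(c("strong", "strong", "weak"), sep = 6, noise = 0)
  d3$flexibility <- c(30, 31, 10)
  m3 <- train_knn(d3, "flexibility", k = 3)
  q <- d3[1, ]; q$flexibility <- 29
  # brute-force: strong is the majority of all three neighbours
  expect_identical(as.character(predict(m3, q)), "strong")

  expect_error(train_knn(d3, "flexibility", k = 4), "n_train")
  expect_error(train_knn(d3, "flexibility", k = 0), "n_train")
})

test_that("LDA matches its closed form on simple geometries", {
  # two spherical classes: the boundary is the perpendicular bisector of
  # the class means (equal priors), checked just either side of the
  # midpoint along the informative feature
  d <- toy_dataset(rep(c("strong", "weak"), each = 25), sep = 6, noise = 1)
  m <- train_lda(d, "flexibility")
  mid <- colMeans(m$means)
  lo <- mid; hi <- mid
  hi["flexibility"] <- mid["flexibility"] + 0.2
  lo["flexibility"] <- mid["flexibility"] - 0.2
  grid <- rbind(hi, lo)
  expect_identical(as.character(predict(m, grid)), c("strong", "weak"))

  # duplicated feature (singular pooled covariance) survives via ridge
  d2 <- d; d2$balance <- d2$flexibility
  expect_s3_class(train_lda(d2, "flexibility"), "fitness_lda")

  expect_error(train_lda(toy_dataset(c("strong", "weak")), "balance"),
               "too few samples")
})

test_that("LDA discriminant scores match hand-computed pooled-covariance form", {
  d <- toy_dataset(c("strong", "strong", "weak", "weak"), sep = 4, noise = 1,
                   seed = 9)
  m <- train_lda(d, "balance")
  x <- feature_matrix(d)
  y <- d$label_balance
  # independent computation from first principles
  mu_s <- colMeans(x[y == "strong", ]); mu_w <- colMeans(x[y == "weak", ])
  centered <- rbind(sweep(x[y == "strong", ], 2, mu_s),
                    sweep(x[y == "weak", ], 2, mu_w))
  S <- crossprod(centered) / (4 - 2)
  Sinv <- tryCatch(solve(S), error = function(e) solve(S + diag(1e-6, 8)))
  score <- function(q, mu) drop(q %*% Sinv %*% mu) -
    drop(mu %*% Sinv %*% mu) / 2 + log(0.5)
  hand <- apply(x, 1, function(q)
    if (score(q, mu_s) >= score(q, mu_w)) "strong" else "weak")
  expect_equal(as.character(predict(m, x)), unname(hand))
})

test_that("classifiers agree with reference implementations on a cohort", {
  skip_if_not_installed("e1071")
  skip_if_not_installed("MASS")
  coh <- generate_cohort(cohort_spec(n_subjects = 200, seed = 21))
  x <- coh[, fitness_features()]
  y <- factor(coh$label_balance, levels = fitness_levels())

  nb_ref <- e1071::naiveBayes(x, y)
  nb <- train_naive_bayes(coh, "balance")
  agree_nb <- mean(predict(nb_ref, x) == predict(nb, coh))
  expect_gte(agree_nb, 0.98)

  lda_ref <- MASS::lda(x, grouping = y)
  lda <- train_lda(coh, "balance")
  agree_lda <- mean(predict(lda_ref, x)$class == predict(lda, coh))
  expect_gte(agree_lda, 0.98)
})

test_that("model sets persist to versioned JSON and round-trip predictions", {
  coh <- generate_cohort(cohort_spec(n_subjects = 120, seed = 13))
  probe <- generate_cohort(cohort_spec(n_subjects = 60, seed = 14))
  for (method in c("naive_bayes", "knn", "lda")) {
    models <- fit_fitness(coh, method)
    path <- withr::local_tempfile(fileext = ".json")
    save_fitness_models(models, path)
    expect_match(readLines(path, warn = FALSE)[1], "\"version\"")
    back <- load_fitness_models(path)
    expect_identical(predict(back, probe), predict(models, probe))
  }
  bad <- withr::local_tempfile(fileext = ".json")
  writeLines('{"format": "something-else"}', bad)
  expect_error(load_fitness_models(bad), "model file")
})
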