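#' Feature and label vocabulary of the fitness-diagnosis pipeline
#'
#' `fitness_features()` returns the fixed instance order of the eight
#' physiological features; `fitness_tests()` the four iFit-style tests
#' that each receive a label; `fitness_levels()` the three-class label
#' alphabet.
#'
#' @return A character vector.
#' @export
fitness_features <- function() {
  c("gender", "age", "weight", "bmi",
    "flexibility", "reaction_time", "grip_strength", "balance")
}

#' @rdname fitness_features
#' @export
fitness_tests <- function() {
  c("flexibility", "balance", "grip_strength", "reaction_time")
}

#' @rdname fitness_features
#' @export
fitness_levels <- function() c("strong", "moderate", "weak")

label_cols <- function() paste0("label_", fitness_tests())

#' Encode a raw physiological record as an instance vector
#'
#' Maps a named record to the fixed 8-slot feature order
#' `[gender, age, weight, bmi, flexibility, reaction_time, grip_strength,
#' balance]` with gender coded male = 1, female = 0. No rescaling happens
#' here; any per-classifier standardisation is done inside training.
#'
#' @param raw A named list or one-row data frame carrying all eight
#'   features.
#' @return A named numeric vector of length 8.
#' @examples
#' preprocess(list(gender = 0, age = 25, weight = 50, bmi = 25,
#'                 flexibility = 29.4, reaction_time = 501,
#'                 grip_strength = 12.2, balance = 5.86))
#' @export
preprocess <- function(raw) {
  feats <- fitness_features()
  raw <- as.list(raw)
  missing <- setdiff(feats, names(raw))
  if (length(missing))
    stop("missing feature(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  v <- vapply(feats, function(f) {
    x <- raw[[f]]
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
      stop("feature `", f, "` must be a single finite number", call. = FALSE)
    as.numeric(x)
  }, numeric(1))
  if (!v[["gender"]] %in% c(0, 1))
    stop("`gender` must be 0 (female) or 1 (male)", call. = FALSE)
  if (any(v < 0))
    stop("features must be non-negative", call. = FALSE)
  v
}

# Coerce a labelled dataset's feature block to an n x 8 numeric matrix.
feature_matrix <- function(data) {
  feats <- fitness_features()
  missing <- setdiff(feats, names(data))
  if (length(missing))
    stop("dataset is missing feature column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  m <- as.matrix(data[, feats, drop = FALSE])
  storage.mode(m) <- "double"
  if (anyNA(m) || any(!is.finite(m)))
    stop("features must be finite and non-missing", call. = FALSE)
  m
}

# Extract the label factor for one fitness test.
test_labels <- function(data, test) {
  test <- match.arg(test, fitness_tests())
  col <- paste0("label_", test)
  if (!col %in% names(data))
    stop("dataset is missing label column `", col, "`", call. = FALSE)
  y <- as.character(data[[col]])
  bad <- setdiff(unique(y), fitness_levels())
  if (length(bad))
    stop("labels outside {strong, moderate, weak}: ",
         paste(bad, collapse = ", "), call. = FALSE)
  factor(y, levels = fitness_levels())
}

#' Train a Gaussian naive Bayes fitness classifier
#'
#' Class-conditional Gaussian model: class priors are the empirical label
#' frequencies; each feature gets a per-class mean and variance (variance
#' floored at 1e-9 so constant features cannot produce degenerate
#' densities). Prediction returns the class with the largest posterior,
#' evaluated in log space.
#'
#' @param data A labelled dataset (feature columns plus `label_*`
#'   columns; see [read_cohort()]).
#' @param test Which fitness test's labels to learn
#'   (`"flexibility"`, `"balance"`, `"grip_strength"`,
#'   `"reaction_time"`).
#' @return A `fitness_nb` model with a [predict()] method.
#' @export
train_naive_bayes <- function(data, test) {
  x <- feature_matrix(data)
  y <- test_labels(data, test)
  present <- levels(y)[tabulate(y, nbins = 3L) > 0L]
  if (length(present) < 2L)
    stop("naive Bayes needs at least two classes present", call. = FALSE)
  stats_by <- lapply(present, function(cl) {
    xs <- x[y == cl, , drop = FALSE]
    v <- apply(xs, 2, stats::var)
    v[is.na(v)] <- 0  # single-member class
    list(mean = colMeans(xs),
         var = pmax(v, 1e-9),
         prior = nrow(xs) / nrow(x))
  })
  names(stats_by) <- present
  structure(list(classes = present, stats = stats_by, test = test),
            class = c("fitness_nb", "fitness_classifier"))
}

#' @export
predict.fitness_nb <- function(object, newdata, ...) {
  x <- if (is.matrix(newdata)) newdata else feature_matrix(newdata)
  scores <- vapply(object$classes, function(cl) {
    s <- object$stats[[cl]]
    log(s$prior) + colSums(stats::dnorm(t(x), s$mean, sqrt(s$var), log = TRUE))
  }, numeric(nrow(x)))
  scores <- matrix(scores, nrow = nrow(x))
  factor(object$classes[max.col(scores, ties.method = "first")],
         levels = fitness_levels())
}

#' Train a k-nearest-neighbour fitness classifier
#'
#' Features are z-scored with the training mean and standard deviation
#' (constant features get unit scale); prediction uses Euclidean distance
#' and majority vote among the `k` nearest training points, with vote
#' ties broken by the class of the single nearest neighbour.
#'
#' @inheritParams train_naive_bayes
#' @param k Number of neighbours (`1 <= k <=` training size).
#' @return A `fitness_knn` model with a [predict()] method.
#' @export
train_knn <- function(data, test, k = 3L) {
  x <- feature_matrix(data)
  y <- test_labels(data, test)
  k <- as.integer(k)
  if (k < 1L || k > nrow(x))
    stop("`k` must lie in [1, n_train]", call. = FALSE)
  center <- colMeans(x)
  scale <- apply(x, 2, stats::sd)
  scale[!is.finite(scale) | scale == 0] <- 1
  structure(list(x = sweep(sweep(x, 2, center), 2, scale, "/"),
                 y = as.character(y), k = k,
                 center = center, scale = scale, test = test),
            class = c("fitness_knn", "fitness_classifier"))
}

#' @export
predict.fitness_knn <- function(object, newdata, ...) {
  x <- if (is.matrix(newdata)) newdata else feature_matrix(newdata)
  x <- sweep(sweep(x, 2, object$center), 2, object$scale, "/")
  out <- character(nrow(x))
  for (i in seq_len(nrow(x))) {
    d <- sqrt(colSums((t(object$x) - x[i, ])^2))
    ord <- order(d)
    nn <- ord[seq_len(object$k)]
    votes <- table(object$y[nn])
    top <- names(votes)[votes == max(votes)]
    out[i] <- if (length(top) == 1L) top else {
      # vote tie: fall back to the nearest single neighbour
      object$y[ord[1L]]
    }
  }
  factor(out, levels = fitness_levels())
}

#' Train a linear discriminant fitness classifier
#'
#' Classic LDA with a pooled within-class covariance matrix and empirical
#' class priors. If the pooled covariance is numerically singular a ridge
#' of 1e-6 is added to its diagonal. Prediction picks the class with the
#' largest linear discriminant score
#' `x' S^-1 m_c - m_c' S^-1 m_c / 2 + log(prior_c)`.
#'
#' @inheritParams train_naive_bayes
#' @return A `fitness_lda` model with a [predict()] method.
#' @export
train_lda <- function(data, test) {
  x <- feature_matrix(data)
  y <- test_labels(data, test)
  present <- levels(y)[tabulate(y, nbins = 3L) > 0L]
  if (length(present) < 2L)
    stop("LDA needs at least two classes present", call. = FALSE)
  if (nrow(x) <= length(present))
    stop("too few samples to estimate the pooled covariance", call. = FALSE)
  means <- t(vapply(present, function(cl) colMeans(x[y == cl, , drop = FALSE]),
                    numeric(ncol(x))))
  centered <- x - means[match(as.character(y), present), , drop = FALSE]
  pooled <- crossprod(centered) / (nrow(x) - length(present))
  inv <- tryCatch(solve(pooled), error = function(e) NULL)
  if (is.null(inv) || !all(is.finite(inv)))
    inv <- solve(pooled + diag(1e-6, ncol(pooled)))
  priors <- as.numeric(table(factor(as.character(y), levels = present))) / nrow(x)
  structure(list(classes = present, means = means, inv_cov = inv,
                 priors = priors, test = test),
            class = c("fitness_lda", "fitness_classifier"))
}

#' @export
predict.fitness_lda <- function(object, newdata, ...) {
  x <- if (is.matrix(newdata)) newdata else feature_matrix(newdata)
  scores <- vapply(seq_along(object$classes), function(j) {
    mu <- object$means[j, ]
    a <- object$inv_cov %*% mu
    drop(x %*% a) - drop(crossprod(mu, a)) / 2 + log(object$priors[j])
  }, numeric(nrow(x)))
  scores <- matrix(scores, nrow = nrow(x))
  factor(object$classes[max.col(scores, ties.method = "first")],
         levels = fitness_levels())
}

#' @export
print.fitness_classifier <- function(x, ...) {
  kind <- c(fitness_nb = "Gaussian naive Bayes",
            fitness_knn = "k-nearest-neighbour",
            fitness_lda = "linear discriminant")[class(x)[1L]]
  cat(sprintf("<%s fitness classifier for the %s test>\n", kind, x$test))
  invisible(x)
}

classifier_methods <- function() c("naive_bayes", "knn", "lda")

# Uniform learner dispatcher used by cross-validation and model sets.
fit_classifier <- function(data, test, method, k = 3L) {
  switch(match.arg(method, classifier_methods()),
         naive_bayes = train_naive_bayes(data, test),
         knn = train_knn(data, test, k = k),
         lda = train_lda(data, test))
}
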