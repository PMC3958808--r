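#' Fit one classifier per fitness test
#'
#' Trains the chosen classifier family on the labels of each of the four
#' fitness tests, yielding the model set the prediction service uses
#' (one model per test, as the diagnosis pipeline deploys four per-test
#' classifiers).
#'
#' @param data A labelled cohort (see [read_cohort()]).
#' @param method `"naive_bayes"` (default, the best-performing family),
#'   `"knn"` or `"lda"`.
#' @param k Neighbour count when `method = "knn"`.
#' @return A `fitness_model_set` with a [predict()] method.
#' @examples
#' coh <- generate_cohort(cohort_spec(seed = 3))
#' models <- fit_fitness(coh)
#' predict(models, coh[1:2, ])
#' @export
fit_fitness <- function(data, method = "naive_bayes", k = 3L) {
  method <- match.arg(method, classifier_methods())
  models <- lapply(fitness_tests(), function(tst)
    fit_classifier(data, tst, method, k = k))
  names(models) <- fitness_tests()
  structure(list(models = models, method = method, version = "1"),
            class = "fitness_model_set")
}

#' @export
print.fitness_model_set <- function(x, ...) {
  cat(sprintf("<fitness_model_set: %s models for %s (format v%s)>\n",
              x$method, paste(names(x$models), collapse = ", "), x$version))
  invisible(x)
}

#' @export
predict.fitness_model_set <- function(object, newdata, ...) {
  x <- if (is.matrix(newdata)) newdata else feature_matrix(newdata)
  out <- lapply(object$models, function(m) as.character(predict(m, x)))
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' Save or load a fitness model set
#'
#' Models are persisted as a versioned JSON document holding the model
#' family and every learned parameter (no opaque native serialisation),
#' so a reloaded set reproduces predictions exactly.
#'
#' @param models A `fitness_model_set`.
#' @param path Path of the JSON file.
#' @return `save_fitness_models()` returns `path` invisibly;
#'   `load_fitness_models()` returns the reconstructed
#'   `fitness_model_set`.
#' @export
save_fitness_models <- function(models, path) {
  payload <- list(
    format = "elasticfit-models",
    version = models$version,
    method = models$method,
    models = lapply(models$models, serialize_model))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

serialize_model <- function(m) {
  base <- list(test = m$test)
  if (inherits(m, "fitness_nb"))
    c(base, list(kind = "naive_bayes", classes = m$classes,
                 stats = lapply(m$stats, function(s)
                   list(mean = s$mean, var = s$var, prior = s$prior))))
  else if (inherits(m, "fitness_knn"))
    c(base, list(kind = "knn", k = m$k, x = m$x, y = m$y,
                 center = m$center, scale = m$scale))
  else
    c(base, list(kind = "lda", classes = m$classes, means = m$means,
                 inv_cov = m$inv_cov, priors = m$priors))
}

#' @rdname save_fitness_models
#' @export
load_fitness_models <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(payload$format, "elasticfit-models"))
    stop("not an elasticfit model file", call. = FALSE)
  models <- lapply(payload$models, deserialize_model)
  names(models) <- vapply(models, `[[`, character(1), "test")
  structure(list(models = models[fitness_tests()], method = payload$method,
                 version = payload$version),
            class = "fitness_model_set")
}

deserialize_model <- function(m) {
  feats <- fitness_features()
  named <- function(v) stats::setNames(as.numeric(v), feats)
  if (m$kind == "naive_bayes") {
    stats_by <- lapply(m$stats, function(s)
      list(mean = named(s$mean), var = named(s$var),
           prior = as.numeric(s$prior)))
    structure(list(classes = m$classes, stats = stats_by[m$classes],
                   test = m$test),
              class = c("fitness_nb", "fitness_classifier"))
  } else if (m$kind == "knn") {
    x <- as.matrix(m$x); colnames(x) <- feats
    structure(list(x = x, y = as.character(m$y), k = as.integer(m$k),
                   center = named(m$center), scale = named(m$scale),
                   test = m$test),
              class = c("fitness_knn", "fitness_classifier"))
  } else if (m$kind == "lda") {
    means <- as.matrix(m$means)
    dimnames(means) <- list(m$classes, feats)
    structure(list(classes = m$classes, means = means,
                   inv_cov = as.matrix(m$inv_cov),
                   priors = as.numeric(m$priors), test = m$test),
              class = c("fitness_lda", "fitness_classifier"))
  } else stop("unknown model kind `", m$kind, "`", call. = FALSE)
}

#' Serve a JSON classification request
#'
#' Decodes a JSON message carrying the eight physiological features (the
#' message format the measurement device posts to the cloud service),
#' validates it, classifies it with the stored per-test models, and
#' returns the JSON response with one strong/moderate/weak label per
#' fitness test. Validation failures produce a structured JSON error
#' response naming the offending field rather than an R error.
#'
#' @param request A JSON string (or path to a JSON file) with exactly the
#'   fields `gender`, `age`, `weight`, `bmi`, `flexibility`,
#'   `reaction_time`, `grip_strength`, `balance`, all numeric.
#' @param models A `fitness_model_set`.
#' @return A JSON string: either
#'   `{"flexibility": "...", "balance": "...", ...}` or
#'   `{"error": "...", "field": "..."}`.
#' @export
predict_json <- function(request, models) {
  err <- function(msg, field = NULL) {
    body <- list(error = msg)
    if (!is.null(field)) body$field <- field
    as.character(jsonlite::toJSON(body, auto_unbox = TRUE))
  }
  parsed <- tryCatch(jsonlite::fromJSON(request, simplifyVector = TRUE),
                     error = function(e) NULL)
  if (is.null(parsed) || !is.list(parsed))
    return(err("request is not a JSON object"))
  feats <- fitness_features()
  missing <- setdiff(feats, names(parsed))
  if (length(missing)) return(err("missing field", missing[1L]))
  extra <- setdiff(names(parsed), feats)
  if (length(extra)) return(err("unknown field", extra[1L]))
  inst <- tryCatch(preprocess(parsed), error = function(e) e)
  if (inherits(inst, "error")) {
    field <- regmatches(conditionMessage(inst),
                        regexpr("`[a-z_]+`", conditionMessage(inst)))
    return(err(conditionMessage(inst),
               if (length(field)) gsub("`", "", field) else NULL))
  }
  labels <- predict(models, matrix(inst, nrow = 1,
                                   dimnames = list(NULL, feats)))
  as.character(jsonlite::toJSON(as.list(labels[1L, ]), auto_unbox = TRUE))
}
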