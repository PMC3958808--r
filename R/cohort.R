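#' Specify a synthetic elder cohort
#'
#' Parameters of the synthetic labelled-cohort generator that emulates
#' the structure of the 85-subject study behind the diagnosis pipeline:
#' adults aged 55-85, 36 male / 49 female, with a strong/moderate/weak
#' expert label per fitness test. The generating model is synthetic; the
#' real study's marginal distributions are unpublished, so every default
#' is declared in the generated dataset's metadata.
#'
#' @param n_subjects Cohort size (>= 12 so each class can appear in every
#'   fold of a 4-fold split).
#' @param male_fraction Expected proportion of males (default 36/85).
#' @param age_range Two-element numeric, low < high, in years.
#' @param separation Class-separation multiplier `delta >= 0`: the
#'   observed score of adjacent label classes differs by `delta` signal
#'   units. 0 removes all label signal from the measurements.
#' @param noise_sd Within-class score noise, in the same signal units
#'   (default 0.55, so the default `separation = 2` places adjacent
#'   classes about 3.6 within-class standard deviations apart).
#' @param seed Integer seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 85L, male_fraction = 36 / 85,
                        age_range = c(55, 85), separation = 2.0,
                        noise_sd = 0.55, seed = 1L) {
  n_subjects <- as.integer(n_subjects)
  if (is.na(n_subjects) || n_subjects < 12L)
    stop("`n_subjects` must be >= 12", call. = FALSE)
  if (male_fraction < 0 || male_fraction > 1)
    stop("`male_fraction` must lie in [0, 1]", call. = FALSE)
  if (length(age_range) != 2L || age_range[1] >= age_range[2])
    stop("`age_range` must be c(low, high) with low < high", call. = FALSE)
  if (separation < 0) stop("`separation` must be >= 0", call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  structure(list(n_subjects = n_subjects, male_fraction = male_fraction,
                 age_range = age_range, separation = separation,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf(
    "<cohort_spec: n=%d, male_fraction=%.3f, age %g-%g, separation=%g, noise_sd=%g, seed=%d>\n",
    x$n_subjects, x$male_fraction, x$age_range[1], x$age_range[2],
    x$separation, x$noise_sd, x$seed))
  invisible(x)
}

# Measurement scales per test: base level, signal-unit size on the
# instrument's scale, and direction (+1 larger = fitter; reaction time
# inverted, larger = slower).
cohort_scales <- function() {
  list(flexibility   = list(base = 28,  unit = 5,   dir = +1, digits = 1),
       reaction_time = list(base = 500, unit = 60,  dir = -1, digits = 0),
       grip_strength = list(base = 22,  unit = 6,   dir = +1, digits = 1),
       balance       = list(base = 6,   unit = 1.5, dir = +1, digits = 2))
}

# Weak age/gender coupling of the latent fitness score: 0.5 latent units
# across the full age range vs latent noise sd 1, so at separation 0 the
# features carry almost no label signal.
cohort_latent_params <- function() {
  list(age_effect = 0.5, gender_effect = 0.1, latent_sd = 1)
}

# Balanced tertile labels from a continuous latent score (high = fitter).
latent_tertiles <- function(latent) {
  n <- length(latent)
  r <- rank(latent, ties.method = "first")
  cls <- character(n)
  cls[r <= n / 3] <- "weak"
  cls[r > n / 3 & r <= 2 * n / 3] <- "moderate"
  cls[r > 2 * n / 3] <- "strong"
  cls
}

#' Generate a synthetic labelled elder cohort
#'
#' Draws demographics (age uniform over the range, gender Bernoulli,
#' weight and BMI from gender-conditional Gaussians), then for each of
#' the four fitness tests builds a latent fitness score that declines
#' weakly with age, labels subjects by the empirical tertiles of that
#' latent (strong / moderate / weak, balanced by construction), and
#' finally emits an observed test measurement whose class mean is offset
#' by `separation` signal units per class step plus Gaussian noise.
#' Reaction time is inverted so that larger values mean slower (less
#' fit). All generator parameters are recorded in the `params` attribute.
#'
#' @param spec A [cohort_spec()].
#' @return A data frame with the eight feature columns, the four
#'   `label_*` columns, and a `params` attribute; reproducible from
#'   `(spec, seed)`.
#' @examples
#' coh <- generate_cohort(cohort_spec(seed = 7))
#' table(coh$label_balance)
#' @export
generate_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec"))
    stop("`spec` must be a cohort_spec", call. = FALSE)
  rng <- local_rng(spec$seed)
  on.exit(rng())
  n <- spec$n_subjects
  lp <- cohort_latent_params()
  age <- sample(seq(spec$age_range[1], spec$age_range[2]), n, replace = TRUE)
  gender <- stats::rbinom(n, 1L, spec$male_fraction)
  weight <- round(ifelse(gender == 1, stats::rnorm(n, 72, 10),
                         stats::rnorm(n, 58, 9)), 1)
  weight <- pmax(weight, 35)
  bmi <- round(ifelse(gender == 1, stats::rnorm(n, 24.5, 3.2),
                      stats::rnorm(n, 23.5, 3.2)), 1)
  bmi <- pmax(bmi, 14)
  age_span <- diff(spec$age_range)
  out <- data.frame(gender = gender, age = age, weight = weight, bmi = bmi)
  scales <- cohort_scales()
  offsets <- c(strong = 1, moderate = 0, weak = -1)
  for (tst in fitness_tests()) {
    latent <- -lp$age_effect * (age - spec$age_range[1]) / age_span +
      lp$gender_effect * gender + stats::rnorm(n, 0, lp$latent_sd)
    label <- latent_tertiles(latent)
    sc <- scales[[tst]]
    score <- sc$base + sc$dir * sc$unit *
      (spec$separation * offsets[label] + stats::rnorm(n, 0, spec$noise_sd))
    out[[tst]] <- pmax(round(score, sc$digits), 0)
    out[[paste0("label_", tst)]] <- label
  }
  out <- out[, c(fitness_features(), label_cols())]
  attr(out, "params") <- c(unclass(spec),
                           list(latent = cohort_latent_params(),
                                scales = cohort_scales()))
  out
}

#' Write or read a labelled cohort as CSV
#'
#' The schema is the eight feature columns followed by the four
#' `label_*` columns. `read_cohort()` rejects files with missing columns,
#' non-finite features, or labels outside the strong/moderate/weak
#' alphabet; round-trips are lossless.
#'
#' @param data A labelled cohort data frame.
#' @param path File path.
#' @return `write_cohort()` returns `path` invisibly; `read_cohort()`
#'   returns the validated data frame.
#' @export
write_cohort <- function(data, path) {
  cols <- c(fitness_features(), label_cols())
  missing <- setdiff(cols, names(data))
  if (length(missing))
    stop("cohort is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  utils::write.csv(data[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  cols <- c(fitness_features(), label_cols())
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop("cohort CSV is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  feature_matrix(df)                 # validates the feature block
  for (tst in fitness_tests()) test_labels(df, tst)
  df[, cols]
}
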