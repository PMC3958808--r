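#' Specify a synthetic request-count pattern
#'
#' Describes one of the four workload shapes used in the autoscaling
#' simulation study: a linear ramp, logarithmic growth, a repetitive
#' (sinusoidal) load, or the combined (mean of linear and repetitive)
#' pattern. Request counts are per-interval totals; the defaults follow
#' the simulation setup of 1,000 intervals with at most 15,000 requests
#' per interval.
#'
#' @param kind One of `"linear"`, `"logarithmic"`, `"repetitive"`,
#'   `"combined"`.
#' @param n_intervals Number of time intervals (>= 1).
#' @param q_max Maximum requests per interval.
#' @param q_min Minimum requests per interval (`0 <= q_min <= q_max`).
#' @param period Cycle length in intervals for the repetitive and combined
#'   patterns (>= 2). Ignored for linear and logarithmic.
#' @param noise_sd Standard deviation of additive Gaussian noise in
#'   requests/interval; 0 disables noise.
#' @param seed Integer seed for the noise draw; required when
#'   `noise_sd > 0` so series are reproducible.
#'
#' @return An object of class `pattern_spec`.
#' @seealso [generate_series()]
#' @export
pattern_spec <- function(kind = c("linear", "logarithmic", "repetitive", "combined"),
                         n_intervals = 1000L, q_max = 15000, q_min = 0,
                         period = 50L, noise_sd = 0, seed = NULL) {
  kind <- match.arg(kind)
  n_intervals <- as.integer(n_intervals)
  if (is.na(n_intervals) || n_intervals < 1L)
    stop("`n_intervals` must be an integer >= 1", call. = FALSE)
  if (!is.numeric(q_max) || !is.numeric(q_min) || q_min < 0 || q_max < q_min)
    stop("need q_max >= q_min >= 0", call. = FALSE)
  if (kind %in% c("repetitive", "combined")) {
    period <- as.integer(period)
    if (is.na(period) || period < 2L)
      stop("`period` must be an integer >= 2 for repetitive/combined patterns",
           call. = FALSE)
  }
  if (!is.numeric(noise_sd) || length(noise_sd) != 1L || noise_sd < 0)
    stop("`noise_sd` must be a single non-negative number", call. = FALSE)
  if (noise_sd > 0 && is.null(seed))
    stop("a `seed` is required when `noise_sd` > 0", call. = FALSE)
  structure(
    list(kind = kind, n_intervals = n_intervals, q_max = q_max, q_min = q_min,
         period = period, noise_sd = noise_sd, seed = seed),
    class = "pattern_spec")
}

#' @export
print.pattern_spec <- function(x, ...) {
  cat(sprintf("<pattern_spec: %s, n=%d, q in [%g, %g]%s%s>\n",
              x$kind, x$n_intervals, x$q_min, x$q_max,
              if (x$kind %in% c("repetitive", "combined"))
                sprintf(", period=%d", x$period) else "",
              if (x$noise_sd > 0)
                sprintf(", noise_sd=%g, seed=%d", x$noise_sd, as.integer(x$seed))
              else ""))
  invisible(x)
}

# Deterministic pattern value before noise/rounding, at intervals t = 1..n.
pattern_values <- function(spec) {
  t <- seq_len(spec$n_intervals)
  n <- spec$n_intervals
  span <- spec$q_max - spec$q_min
  linear <- if (n == 1L) rep(spec$q_max, 1L) else
    spec$q_min + span * (t - 1) / (n - 1)
  switch(spec$kind,
    linear      = linear,
    logarithmic = spec$q_min + span * log(1 + t) / log(1 + n),
    repetitive  = spec$q_min + span * (1 + sin(2 * pi * t / spec$period)) / 2,
    combined    = {
      repv <- spec$q_min + span * (1 + sin(2 * pi * t / spec$period)) / 2
      (linear + repv) / 2
    })
}

#' Generate a synthetic request-count series
#'
#' Evaluates the deterministic pattern described by a [pattern_spec()],
#' optionally adds seeded Gaussian noise, then rounds half-up to integer
#' counts and clips to `[q_min, q_max]`.
#'
#' The pattern shapes are: linear, an affine ramp from `q_min` at the first
#' interval to `q_max` at the last; logarithmic,
#' `q_min + (q_max - q_min) * log(1 + t) / log(1 + n)`; repetitive, a
#' sinusoid `q_min + (q_max - q_min) * (1 + sin(2 * pi * t / period)) / 2`;
#' combined, the arithmetic mean of the linear and repetitive values.
#'
#' @param spec A [pattern_spec()].
#' @return An integer vector of class `request_series`, one non-negative
#'   request count per interval.
#' @examples
#' q <- generate_series(pattern_spec("linear", n_intervals = 100, q_max = 500))
#' range(q)
#' @export
generate_series <- function(spec) {
  if (!inherits(spec, "pattern_spec"))
    stop("`spec` must be a pattern_spec", call. = FALSE)
  v <- pattern_values(spec)
  if (spec$noise_sd > 0) {
    rng <- local_rng(spec$seed)
    on.exit(rng())
    v <- v + stats::rnorm(length(v), sd = spec$noise_sd)
  }
  q <- as.integer(pmin(pmax(floor(v + 0.5), spec$q_min), spec$q_max))
  structure(q, class = "request_series")
}

#' @export
print.request_series <- function(x, ...) {
  cat(sprintf("<request_series: %d intervals, range [%d, %d]>\n",
              length(x), min(x), max(x)))
  invisible(x)
}

as_request_series <- function(q) {
  if (length(q) < 1L) stop("a request series must have at least one interval",
                           call. = FALSE)
  if (anyNA(q) || any(q != floor(q)) || any(q < 0))
    stop("request counts must be non-negative integers", call. = FALSE)
  structure(as.integer(q), class = "request_series")
}

#' Write or read a request series as CSV
#'
#' The file has a single `requests` column with a header row, one row per
#' interval. `read_series()` validates that every value is a non-negative
#' integer and that the series is non-empty; round-trips are lossless.
#'
#' @param series An integer request-count vector (e.g. from
#'   [generate_series()]).
#' @param path File path.
#' @return `write_series()` returns `path` invisibly; `read_series()`
#'   returns a `request_series`.
#' @export
write_series <- function(series, path) {
  utils::write.csv(data.frame(requests = as.integer(series)), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_series
#' @export
read_series <- function(path) {
  df <- tryCatch(utils::read.csv(path),
                 error = function(e) stop("malformed series CSV: ",
                                          conditionMessage(e), call. = FALSE))
  if (!"requests" %in% names(df))
    stop("series CSV must have a `requests` column", call. = FALSE)
  q <- df$requests
  if (length(q) < 1L) stop("series CSV is empty", call. = FALSE)
  if (!is.numeric(q) || anyNA(q) || any(q != floor(q)) || any(q < 0))
    stop("request counts must be non-negative integers", call. = FALSE)
  as_request_series(q)
}

# Seed the RNG locally; returns a restore function for on.exit.
local_rng <- function(seed) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed))
  function() {
    if (had) assign(".Random.seed", old, envir = globalenv())
    else rm(".Random.seed", envir = globalenv())
  }
}
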