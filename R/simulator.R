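#' Run the elastic allocator over a request series
#'
#' Drives the autoscaler in one-step-ahead mode: the units applied during
#' interval `t` are decided from the observations up to `t - 1`, so the
#' first interval runs with `u_min` units and the state after processing
#' `q[t-1]` sets the capacity for interval `t`. The run is deterministic
#' given `(series, config)`.
#'
#' @param series A request-count vector (e.g. from [generate_series()]).
#' @param config An [allocator_config()].
#' @return A `sim_trace` data frame with one row per interval and columns
#'   `t`, `requests`, `lambda` (the EMA estimate the allocation for `t`
#'   was based on; `NA` for the first interval), `units`, `capacity`
#'   (`units * C`), and `violation` (1 when requests exceed capacity).
#' @examples
#' tr <- run_simulation(generate_series(pattern_spec("linear", 100, 500)),
#'                      allocator_config(C = 10, u_max = 60))
#' summary(tr)
#' @export
run_simulation <- function(series, config = allocator_config()) {
  q <- as.integer(series)
  if (length(q) < 1L) stop("`series` must be non-empty", call. = FALSE)
  if (anyNA(q) || any(q < 0)) stop("request counts must be non-negative",
                                   call. = FALSE)
  n <- length(q)
  units <- integer(n)
  lambda <- rep(NA_real_, n)
  state <- allocator_state(config$u_min, config = config)
  units[1L] <- config$u_min
  for (t in seq_len(n)) {
    if (t >= 2L) {
      units[t] <- state$units
      lambda[t] <- state$lam
    }
    state <- allocate_step(state, q[t], config)
  }
  trace <- data.frame(t = seq_len(n), requests = q, lambda = lambda,
                      units = units, capacity = units * config$C,
                      violation = as.integer(q > units * config$C))
  attr(trace, "config") <- config
  class(trace) <- c("sim_trace", "data.frame")
  trace
}

#' Mean absolute percentage error
#'
#' `(100 / n') * sum(|A_t - F_t| / A_t)` over the `n'` intervals with
#' actual value `A_t > 0`; intervals with zero actual demand are skipped
#' because the relative error is undefined there. Returns 0 when no
#' interval has positive demand.
#'
#' @param actual Observed values (here: requests per interval).
#' @param predicted Predicted/provided values (here: capacity per
#'   interval).
#' @return The MAPE in percent (>= 0).
#' @export
mape <- function(actual, predicted) {
  if (length(actual) != length(predicted))
    stop("`actual` and `predicted` must have equal length", call. = FALSE)
  if (length(actual) < 1L) stop("need at least one observation", call. = FALSE)
  keep <- actual > 0
  if (!any(keep)) return(0)
  mean(abs(actual[keep] - predicted[keep]) / actual[keep]) * 100
}

#' Summarise a simulation trace
#'
#' Computes the MAPE between actual requests and provided capacity, the
#' number of quality-of-service violations (intervals where requests
#' exceeded capacity), and the mean and maximum number of assigned units.
#'
#' @param object A `sim_trace` from [run_simulation()].
#' @param ... Unused.
#' @return A `sim_summary` list with elements `mape_percent`,
#'   `violation_count`, `mean_units`, `max_units`, `n_intervals`.
#' @export
summary.sim_trace <- function(object, ...) {
  structure(
    list(mape_percent = mape(object$requests, object$capacity),
         violation_count = sum(object$requests > object$capacity),
         mean_units = mean(object$units),
         max_units = max(object$units),
         n_intervals = nrow(object)),
    class = "sim_summary")
}

#' @export
print.sim_summary <- function(x, ...) {
  cat(sprintf(paste0(
    "Elastic allocation over %d intervals\n",
    "  MAPE (requests vs capacity): %.2f%%\n",
    "  QoS violations:              %d intervals\n",
    "  assigned units:              mean %.2f, max %d\n"),
    x$n_intervals, x$mape_percent, x$violation_count, x$mean_units,
    x$max_units))
  invisible(x)
}

#' Plot a simulation trace
#'
#' Overlays provided capacity on the actual request counts.
#'
#' @param x A `sim_trace`.
#' @param ... Passed to [plot()].
#' @export
plot.sim_trace <- function(x, ...) {
  plot(x$t, x$requests, type = "l", xlab = "interval", ylab = "requests",
       ...)
  graphics::lines(x$t, x$capacity, lty = 2)
  graphics::legend("topleft", legend = c("requests", "capacity"),
                   lty = c(1, 2), bty = "n")
  invisible(x)
}

#' Write or read a simulation trace as CSV
#'
#' The header is exactly `t,requests,lambda,units,capacity,violation`;
#' the violation flag is serialised as 0/1. Integer columns round-trip
#' losslessly.
#'
#' @param trace A `sim_trace`.
#' @param path File path.
#' @return `write_trace()` returns `path` invisibly; `read_trace()`
#'   returns a `sim_trace` (without the config attribute).
#' @export
write_trace <- function(trace, path) {
  utils::write.csv(as.data.frame(trace)[, c("t", "requests", "lambda",
                                            "units", "capacity", "violation")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  df <- utils::read.csv(path)
  need <- c("t", "requests", "lambda", "units", "capacity", "violation")
  if (!identical(names(df), need))
    stop("trace CSV must have columns ", paste(need, collapse = ","),
         call. = FALSE)
  for (col in c("t", "requests", "units", "violation"))
    df[[col]] <- as.integer(df[[col]])
  df$capacity <- as.numeric(df$capacity)
  class(df) <- c("sim_trace", "data.frame")
  df
}
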