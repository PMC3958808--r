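#' Configure the elastic allocation policy
#'
#' Parameters of the Poisson-threshold autoscaler. Each computational unit
#' (virtual machine/worker) serves `C` requests per time interval, so `U`
#' running units provide capacity `U * C`. Demand is forecast by an
#' exponential moving average (EMA) of observed request counts with
#' smoothing weight `alpha = 2 / (w + 1)`; units are added when the
#' Poisson probability that demand exceeds current capacity passes
#' `thre_i`, and released when the probability that a smaller pool still
#' covers demand passes `thre_d`.
#'
#' @param C Requests one unit can process per interval (>= 1).
#' @param I Maximum units that may be added or removed in one step
#'   (default: `u_max`).
#' @param thre_i Threshold in `[0, 1]` for increasing units.
#' @param thre_d Threshold in `[0, 1]` for decreasing units.
#' @param w EMA window length in intervals (>= 1); the smoothing weight is
#'   `2 / (w + 1)`.
#' @param u_min Minimum number of running units (>= 1).
#' @param u_max Maximum number of running units.
#'
#' @return An object of class `allocator_config`.
#' @examples
#' allocator_config()           # the simulation-study defaults
#' @export
allocator_config <- function(C = 100, I = u_max, thre_i = 0.2, thre_d = 0.2,
                             w = 5, u_min = 1L, u_max = 150L) {
  u_min <- as.integer(u_min); u_max <- as.integer(u_max)
  if (!is.numeric(C) || C < 1) stop("`C` must be >= 1", call. = FALSE)
  if (u_min < 1L || u_max < u_min)
    stop("need 1 <= u_min <= u_max", call. = FALSE)
  I <- as.integer(I)
  if (is.na(I) || I < 1L) stop("`I` must be an integer >= 1", call. = FALSE)
  if (thre_i < 0 || thre_i > 1 || thre_d < 0 || thre_d > 1)
    stop("thresholds must lie in [0, 1]", call. = FALSE)
  if (!is.numeric(w) || w < 1) stop("`w` must be >= 1", call. = FALSE)
  structure(list(C = C, I = I, thre_i = thre_i, thre_d = thre_d, w = w,
                 u_min = u_min, u_max = u_max),
            class = "allocator_config")
}

#' @export
print.allocator_config <- function(x, ...) {
  cat(sprintf(
    "<allocator_config: C=%g, I=%d, thre_i=%g, thre_d=%g, w=%g, units in [%d, %d]>\n",
    x$C, x$I, x$thre_i, x$thre_d, x$w, x$u_min, x$u_max))
  invisible(x)
}

#' Read an allocator configuration from JSON
#'
#' Accepts a flat JSON object with any subset of the [allocator_config()]
#' keys; missing keys take the defaults, unknown keys are rejected.
#'
#' @param path Path to a JSON file.
#' @return An `allocator_config`.
#' @export
read_allocator_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(allocator_config))
  extra <- setdiff(names(raw), known)
  if (length(extra))
    stop("unknown allocator config keys: ", paste(extra, collapse = ", "),
         call. = FALSE)
  do.call(allocator_config, raw)
}

#' Allocator state
#'
#' The evolving state of the autoscaler: the EMA demand estimate `lam`
#' (mean requests per interval), the number of running units, and the
#' interval index. A fresh state starts with `lam = NA`; the first
#' observation initialises the EMA directly (full weight on the first
#' observed count).
#'
#' @param units Current running units.
#' @param lam EMA estimate of mean requests per interval, or `NA` before
#'   the first observation.
#' @param t Interval index of the last processed observation.
#' @param config An [allocator_config()]; used to validate bounds.
#' @return An object of class `allocator_state`.
#' @export
allocator_state <- function(units, lam = NA_real_, t = 0L, config = allocator_config()) {
  units <- as.integer(units)
  if (units < config$u_min || units > config$u_max)
    stop("`units` outside [u_min, u_max]", call. = FALSE)
  if (!is.na(lam) && lam < 0) stop("`lam` must be >= 0", call. = FALSE)
  structure(list(lam = lam, units = units, t = as.integer(t)),
            class = "allocator_state")
}

#' @export
print.allocator_state <- function(x, ...) {
  cat(sprintf("<allocator_state: t=%d, units=%d, lambda=%s>\n",
              x$t, x$units, if (is.na(x$lam)) "NA" else format(x$lam)))
  invisible(x)
}

#' EMA smoothing weight from the window length
#'
#' @param w Window length in intervals (>= 1).
#' @return The smoothing weight `2 / (w + 1)`, in `(0, 1]`.
#' @export
smoothing_alpha <- function(w) {
  if (!is.numeric(w) || any(w < 1)) stop("`w` must be >= 1", call. = FALSE)
  2 / (w + 1)
}

#' One exponential-moving-average update
#'
#' Returns `alpha * q + (1 - alpha) * lam_prev`, the EMA of the request
#' counts after observing `q`.
#'
#' @param q Observed request count (>= 0).
#' @param lam_prev Previous EMA value (>= 0).
#' @param alpha Smoothing weight in `(0, 1]`.
#' @return The updated estimate.
#' @export
ema_update <- function(q, lam_prev, alpha) {
  if (any(q < 0) || any(lam_prev < 0))
    stop("`q` and `lam_prev` must be >= 0", call. = FALSE)
  if (any(alpha <= 0) || any(alpha > 1))
    stop("`alpha` must lie in (0, 1]", call. = FALSE)
  alpha * q + (1 - alpha) * lam_prev
}

#' Poisson probability mass and upper-tail probability
#'
#' `poisson_pmf(k, lam)` is `P(X = k)` and `poisson_tail(k, lam)` is
#' `P(X > k)` for `X ~ Poisson(lam)`, evaluated stably in log space so
#' that large means (thousands of requests) are handled without under- or
#' overflow.
#'
#' @param k Non-negative integer count (vectorised).
#' @param lam Poisson mean (>= 0).
#' @return Probabilities in `[0, 1]`.
#' @export
poisson_pmf <- function(k, lam) {
  if (any(k < 0) || any(k != floor(k))) stop("`k` must be a non-negative integer",
                                             call. = FALSE)
  if (any(lam < 0)) stop("`lam` must be >= 0", call. = FALSE)
  stats::dpois(k, lam)
}

#' @rdname poisson_pmf
#' @export
poisson_tail <- function(k, lam) {
  if (any(k < 0) || any(k != floor(k))) stop("`k` must be a non-negative integer",
                                             call. = FALSE)
  if (any(lam < 0)) stop("`lam` must be >= 0", call. = FALSE)
  pmin(pmax(stats::ppois(k, lam, lower.tail = FALSE), 0), 1)
}

#' Scaling-decision probabilities
#'
#' `prob_need_increase(i, ...)` is the probability that demand exceeds
#' what `U + i - 1` units can serve, i.e. that at least `i` additional
#' units are needed: `P(X > (U + i - 1) * C | lam)`.
#' `prob_can_decrease(i, ...)` is the probability that `U - i` units still
#' cover demand: `P(X <= (U - i) * C | lam)`. Both are non-increasing in
#' `i` (nested tail events).
#'
#' @param i Candidate unit delta; `1 <= i <= I` for increase,
#'   `1 <= i <= min(I, U - u_min)` for decrease.
#' @param state An [allocator_state()] with a non-`NA` demand estimate.
#' @param config An [allocator_config()].
#' @return A probability.
#' @export
prob_need_increase <- function(i, state, config) {
  if (any(i < 1) || any(i > config$I))
    stop("`i` must lie in [1, I]", call. = FALSE)
  poisson_tail((state$units + i - 1) * config$C, state$lam)
}

#' @rdname prob_need_increase
#' @export
prob_can_decrease <- function(i, state, config) {
  if (any(i < 1) || any(i > min(config$I, state$units - config$u_min)))
    stop("`i` must lie in [1, min(I, U - u_min)]", call. = FALSE)
  1 - poisson_tail((state$units - i) * config$C, state$lam)
}

#' Advance the allocator by one interval
#'
#' Updates the EMA demand estimate with the observed request count, then
#' decides the unit change for the next interval: scanning candidate
#' deltas from `I` down to 1, the largest `i` whose increase probability
#' exceeds `thre_i` adds `i` units; otherwise the largest `i` whose
#' decrease probability exceeds `thre_d` removes `i` units; otherwise the
#' pool is unchanged. The increase branch has priority, at most one branch
#' fires per step, and the result is clamped to `[u_min, u_max]`.
#'
#' @param state An [allocator_state()].
#' @param q_observed Requests observed in the current interval (>= 0).
#' @param config An [allocator_config()].
#' @return The new `allocator_state`.
#' @export
allocate_step <- function(state, q_observed, config) {
  if (q_observed < 0) stop("`q_observed` must be >= 0", call. = FALSE)
  lam <- if (is.na(state$lam)) as.numeric(q_observed)
         else ema_update(q_observed, state$lam, smoothing_alpha(config$w))
  U <- state$units
  # Vectorised scan over deltas I..1: largest qualifying delta wins.
  inc_p <- poisson_tail((U + seq_len(config$I) - 1) * config$C, lam)
  inc <- which(inc_p > config$thre_i)
  if (length(inc)) {
    U <- U + max(inc)
  } else {
    d_max <- min(config$I, U - config$u_min)
    if (d_max >= 1L) {
      dec_p <- 1 - poisson_tail((U - seq_len(d_max)) * config$C, lam)
      dec <- which(dec_p > config$thre_d)
      if (length(dec)) U <- U - max(dec)
    }
  }
  U <- min(max(U, config$u_min), config$u_max)
  structure(list(lam = lam, units = as.integer(U), t = state$t + 1L),
            class = "allocator_state")
}
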