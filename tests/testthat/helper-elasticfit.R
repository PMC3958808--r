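# Independent Poisson CDF oracle: term-by-term cumulative summation of
# the pmf in log space (log-sum-exp), deliberately not using dpois/ppois.
oracle_pois_cdf <- function(k, lam) {
  if (lam == 0) return(1)
  j <- 0:k
  log_terms <- j * log(lam) - lam - lgamma(j + 1)
  m <- max(log_terms)
  exp(m) * sum(exp(log_terms - m))
}
oracle_pois_tail <- function(k, lam) 1 - oracle_pois_cdf(k, lam)

# Smallest unit count whose capacity covers Poisson(q) demand with
# exceedance probability at most `thre` (direct search).
oracle_u_star <- function(q, C, thre) {
  u <- 1L
  while (oracle_pois_tail(u * C, q) > thre) u <- u + 1L
  u
}

# Tiny labelled frame: the four test scores carry the class signal
# (shifted by `sep` per class step), remaining features are benign
# demographics. All four label columns share the same labels.
toy_dataset <- function(labels, sep = 6, noise = 0.5, seed = 42) {
  stopifnot(all(labels %in% fitness_levels()))
  n <- length(labels)
  offset <- c(strong = 1, moderate = 0, weak = -1)[labels]
  set.seed(seed)
  df <- data.frame(
    gender = rep_len(c(0, 1), n),
    age = rep_len(c(60, 70, 80), n),
    weight = rep_len(c(55, 70), n),
    bmi = rep_len(c(22, 26), n),
    flexibility = 28 + sep * offset + rnorm(n, 0, noise),
    reaction_time = 500 - 50 * sep / 6 * offset + rnorm(n, 0, 10 * noise),
    grip_strength = 22 + sep * offset + rnorm(n, 0, noise),
    balance = 6 + sep / 4 * offset + rnorm(n, 0, noise / 4))
  for (tst in fitness_tests()) df[[paste0("label_", tst)]] <- labels
  df
}

worked_record <- function() {
  list(gender = 0, age = 25, weight = 50, bmi = 25, flexibility = 29.4,
       reaction_time = 501, grip_strength = 12.2, balance = 5.86)
}
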