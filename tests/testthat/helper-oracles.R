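# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths: quantiles from first principles, gates
# by direct per-event rule application, test p-values by exhaustive
# enumeration.

# p-quantile by explicit interpolation at rank 1 + p*(n-1) on sorted values
oracle_quantile <- function(x, p) {
  s <- sort(x)
  n <- length(s)
  h <- 1 + p * (n - 1)
  lo <- floor(h)
  hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

# RPI recomputed from raw values: rescale alpha's P95 across beta's IQR
oracle_rpi <- function(alpha_values, beta_values) {
  p95 <- oracle_quantile(alpha_values, 0.95)
  q1 <- oracle_quantile(beta_values, 0.25)
  q3 <- oracle_quantile(beta_values, 0.75)
  if (q3 == q1) return(if (p95 < q1) 0 else 1)
  min(1, max(0, (p95 - q1) / (q3 - q1)))
}

# event ids surviving a top-fraction gate, by explicit pairwise ranking:
# an event survives iff fewer than k events beat it (brighter, or equally
# bright with a smaller original index)
oracle_top_fraction_ids <- function(x, ids, fraction) {
  n <- length(x)
  k <- ceiling(fraction * n)
  beats <- vapply(seq_len(n), function(i) {
    sum(x > x[i] | (x == x[i] & seq_len(n) < i))
  }, numeric(1))
  ids[beats < k]
}

oracle_threshold_ids <- function(x, ids, cutoff, direction) {
  if (direction == "above") ids[x > cutoff] else ids[x < cutoff]
}

# Wilcoxon signed-rank two-sided exact p by enumerating all 2^n sign
# assignments (zeros dropped, midranks for ties)
oracle_wilcoxon_p <- function(x, y) {
  d <- (x - y)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(1)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  ws <- as.numeric(signs %*% r)
  p_le <- mean(ws <= w_obs + 1e-9)
  p_ge <- mean(ws >= w_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# Mann-Whitney two-sided exact p by enumerating all C(n, n1) labelings of
# the pooled midranks
oracle_mann_whitney_p <- function(x, y) {
  n1 <- length(x)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  subsets <- combn(length(r), n1)
  us <- apply(subsets, 2, function(idx) sum(r[idx])) - n1 * (n1 + 1) / 2
  p_le <- mean(us <= u_obs + 1e-9)
  p_ge <- mean(us >= u_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# configured log10 location + drift offset, recomputed from the config's
# public tables (independent of the package's internal lookup)
model_location_public <- function(cfg, class, channel, day) {
  cm <- cfg$channel_models
  base <- cm$location[cm$class == class & cm$channel == channel]
  d <- cfg$drifts
  hit <- d$class == class & d$channel == channel & d$day == day
  base + if (any(hit)) d$offset[hit][1] else 0
}

# small labeled table with chosen intensities on one channel
make_table <- function(values, labels = NULL, channel = "CD133",
                       timepoint = NULL) {
  m <- matrix(values, ncol = 1, dimnames = list(NULL, channel))
  event_table(m, labels = labels, timepoint = timepoint)
}

# random labeled fixture on one channel, <= 50 events
random_fixture <- function(n, channel = "CD133") {
  labels <- sample(cell_classes(), n, replace = TRUE)
  # duplicated values with 30% probability so ties get exercised
  vals <- 10^stats::runif(n, 1, 4)
  dup <- stats::runif(n) < 0.3
  if (any(dup) && n > 1) {
    vals[dup] <- sample(vals[!dup | seq_len(n) == 1], sum(dup),
                        replace = TRUE)
  }
  make_table(vals, labels = labels, channel = channel)
}
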