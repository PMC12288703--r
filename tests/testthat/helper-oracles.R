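# Brute-force oracles, written independently of the package internals:
# plain loops over explicit phase splits.

# phase mean difference for one start, NA-dropping, loop arithmetic
oracle_D <- function(day, value, s) {
  a <- c()
  b <- c()
  for (i in seq_along(day)) {
    if (is.na(value[i])) next
    if (day[i] < s) a <- c(a, value[i]) else b <- c(b, value[i])
  }
  if (length(a) == 0 || length(b) == 0) return(NA_real_)
  sum(b) / length(b) - sum(a) / length(a)
}

# exhaustive individual randomization distribution and one-sided (less) p
oracle_individual <- function(day, value, starts, obs_start) {
  ds <- sapply(starts, function(s) oracle_D(day, value, s))
  keep <- !is.na(ds)
  ds <- ds[keep]
  obs <- oracle_D(day, value, obs_start)
  list(dist = ds, observed = obs, p = sum(ds <= obs) / length(ds))
}

# exhaustive combined distribution over the joint start space
oracle_combined <- function(series_list, starts, obs_starts) {
  d_tabs <- lapply(series_list, function(s) {
    ds <- sapply(starts, function(k) oracle_D(s$day, s$value, k))
    ds[!is.na(ds)]
  })
  grid <- do.call(expand.grid, lapply(d_tabs, seq_along))
  dist <- apply(grid, 1, function(idx) {
    mean(mapply(function(tab, i) tab[i], d_tabs, idx))
  })
  obs <- mean(mapply(function(s, k) oracle_D(s$day, s$value, k),
                     series_list, obs_starts))
  list(dist = dist, observed = obs, p = sum(dist <= obs) / length(dist))
}

# small wide-randomization design used for individual null calibration
wide_design <- function() {
  study_design(total_days = 28, baseline_min = 3, baseline_max = 22)
}

binomial_ci <- function(p, n, level = 0.95) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  se <- sqrt(p * (1 - p) / n)
  c(p - z * se, p + z * se)
}
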