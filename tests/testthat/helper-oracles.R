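# Independent oracles used across the suite.  These deliberately use the
# slowest, most transparent formulation available (double loops, direct
# sums, exhaustive enumeration) so they share no code path with the
# package implementations they check.

# O(n^2)-style slice extents: quantize z, then for each slice loop over
# every point to find the four extremes.
oracle_slice_extents <- function(xyz, slice_width, min_points) {
  z <- xyz[, 3]
  idx <- floor((z - min(z)) / slice_width)
  out <- NULL
  for (k in sort(unique(idx))) {
    xs <- c(); ys <- c()
    for (i in seq_len(nrow(xyz)))
      if (idx[i] == k) { xs <- c(xs, xyz[i, 1]); ys <- c(ys, xyz[i, 2]) }
    if (length(xs) >= min_points)
      out <- rbind(out, c(k = k, n = length(xs),
                          dim_x = max(xs) - min(xs),
                          dim_y = max(ys) - min(ys)))
  }
  as.data.frame(out)
}

# exhaustive 1-D 2-means: try every threshold cut in sorted order and
# return the minimal within-cluster sum of squares
oracle_best_cut_wss <- function(values) {
  v <- sort(values)
  n <- length(v)
  best <- Inf
  for (m in 1:(n - 1)) {
    lo <- v[1:m]; hi <- v[(m + 1):n]
    wss <- sum((lo - mean(lo))^2) + sum((hi - mean(hi))^2)
    if (wss < best) best <- wss
  }
  best
}

# textbook simple OLS by normal equations
oracle_ols <- function(x, y) {
  n <- length(x)
  sxx <- sum(x^2) - sum(x)^2 / n
  sxy <- sum(x * y) - sum(x) * sum(y) / n
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  yhat <- intercept + slope * x
  r2 <- 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
  list(slope = slope, intercept = intercept, r_squared = r2)
}

# one-way ANOVA by direct summation over a list of groups
oracle_anova <- function(groups) {
  all_v <- unlist(groups)
  grand <- sum(all_v) / length(all_v)
  ss_b <- 0; ss_w <- 0
  for (g in groups) {
    gm <- sum(g) / length(g)
    ss_b <- ss_b + length(g) * (gm - grand)^2
    for (v in g) ss_w <- ss_w + (v - gm)^2
  }
  list(ss_between = ss_b, ss_within = ss_w,
       f = (ss_b / (length(groups) - 1)) /
         (ss_w / (length(all_v) - length(groups))))
}

# noise-free generator shortcut used throughout
quiet_noise <- function(density = 1.0, jitter = 0)
  noise_model(jitter_sd_mm = jitter, outlier_rate = 0,
              density_pts_per_mm2 = density)
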