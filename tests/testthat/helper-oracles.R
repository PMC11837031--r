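# Independent brute-force oracles. Deliberately naive (triple loops, explicit
# sort-and-interpolate) so they share no code path with the implementation.

# volume of weighted/binary voxels: plain triple loop
oracle_volume <- function(weights, voxel_size) {
  d <- dim(weights)
  total <- 0
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    total <- total + weights[i, j, k]
  }
  total * voxel_size[1] * voxel_size[2] * voxel_size[3]
}

# number of voxels where both masks are 1
oracle_overlap_count <- function(a, b) {
  d <- dim(a)
  n <- 0L
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (a[i, j, k] == 1 && b[i, j, k] == 1) n <- n + 1L
  }
  n
}

oracle_weighted_mean <- function(metric, weights) {
  d <- dim(metric)
  num <- 0
  den <- 0
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    num <- num + metric[i, j, k] * weights[i, j, k]
    den <- den + weights[i, j, k]
  }
  if (den == 0) NA_real_ else num / den
}

# percentile by linear interpolation between closest order statistics
oracle_percentile <- function(values, p) {
  v <- sort(values)
  n <- length(v)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  v[lo] + (h - lo) * (v[hi] - v[lo])
}

oracle_psmd <- function(md, skeleton, lo = 0.05, hi = 0.95) {
  vals <- c()
  d <- dim(md)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (skeleton[i, j, k] == 1) vals <- c(vals, md[i, j, k])
  }
  oracle_percentile(vals, hi) - oracle_percentile(vals, lo)
}

# DSE components computed voxel by voxel from the definitions
oracle_dse <- function(bold) {
  d <- dim(bold)
  n_t <- d[4]
  y <- matrix(bold, ncol = n_t)
  y <- y - rowMeans(y)
  n_v <- nrow(y)
  a <- numeric(n_t); dd <- numeric(n_t - 1); ss <- numeric(n_t - 1)
  for (t in seq_len(n_t)) a[t] <- sum(y[, t]^2) / n_v
  for (t in seq_len(n_t - 1)) {
    dd[t] <- sum(((y[, t + 1] - y[, t]) / 2)^2) / n_v
    ss[t] <- sum(((y[, t + 1] + y[, t]) / 2)^2) / n_v
  }
  e <- (sum(y[, 1]^2) + sum(y[, n_t]^2)) / (2 * n_v)
  list(a = a, d = dd, s = ss, e = e)
}

oracle_simes <- function(p) {
  m <- length(p)
  ps <- sort(p)
  best <- Inf
  for (i in seq_len(m)) best <- min(best, m * ps[i] / i)
  min(1, best)
}

# BH by exhaustive threshold search over the observed p-values
oracle_bh_reject <- function(p, q) {
  m <- length(p)
  thresh <- -Inf
  for (cand in p) {
    k <- sum(p <= cand)
    if (cand <= k * q / m && cand > thresh) thresh <- cand
  }
  p <= thresh
}

# shared small fixtures -------------------------------------------------------

random_grid <- function(seed, shape = c(16, 16, 16), vox = c(2, 2, 2),
                        lo = 0, hi = 1) {
  withr::with_seed(seed, {
    volume_grid(array(runif(prod(shape), lo, hi), shape), vox)
  })
}

random_mask <- function(seed, shape = c(16, 16, 16), vox = c(2, 2, 2),
                        p = 0.3) {
  withr::with_seed(seed, {
    volume_grid(array(as.numeric(rbinom(prod(shape), 1, p)), shape), vox)
  })
}
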