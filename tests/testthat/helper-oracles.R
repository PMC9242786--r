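# Naive loop-based reference implementations, independent of the package's
# vectorized code paths. Deliberately written as plain accumulation loops.

naive_rms <- function(mg) {
  acc <- 0
  for (v in mg) acc <- acc + v * v
  sqrt(acc / length(mg))
}

naive_range <- function(mg) {
  lo <- Inf; hi <- -Inf
  for (v in mg) {
    if (v < lo) lo <- v
    if (v > hi) hi <- v
  }
  hi - lo
}

naive_ac <- function(mg, fs) {
  acc <- 0
  for (v in mg) acc <- acc + v
  acc / fs
}

naive_sd_metric <- function(mg) {
  acc <- 0
  for (i in 2:length(mg)) acc <- acc + abs(mg[i] - mg[i - 1])
  acc
}

naive_path <- function(x, y) {
  acc <- 0
  for (i in 2:length(x)) {
    acc <- acc + sqrt((x[i] - x[i - 1])^2 + (y[i] - y[i - 1])^2)
  }
  acc
}

naive_magnitude <- function(gx, gy, gz) {
  out <- numeric(length(gx))
  for (i in seq_along(gx)) out[i] <- sqrt(gx[i]^2 + gy[i]^2 + gz[i]^2)
  out
}

# mid-ranks computed by counting, then Pearson by explicit sums
naive_midrank <- function(x) {
  n <- length(x)
  r <- numeric(n)
  for (i in seq_len(n)) {
    below <- 0; equal <- 0
    for (j in seq_len(n)) {
      if (x[j] < x[i]) below <- below + 1
      if (x[j] == x[i]) equal <- equal + 1
    }
    r[i] <- below + (equal + 1) / 2
  }
  r
}

naive_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  sxy <- 0; sxx <- 0; syy <- 0
  for (i in seq_len(n)) {
    sxy <- sxy + (x[i] - mx) * (y[i] - my)
    sxx <- sxx + (x[i] - mx)^2
    syy <- syy + (y[i] - my)^2
  }
  sxy / sqrt(sxx * syy)
}

naive_spearman <- function(x, y) {
  naive_pearson(naive_midrank(x), naive_midrank(y))
}

# explicit two-way ANOVA mean squares for an n x 2 layout
naive_icc21 <- function(a, b) {
  n <- length(a); k <- 2
  dat <- cbind(a, b)
  grand <- sum(dat) / (n * k)
  ssr <- 0
  for (i in seq_len(n)) ssr <- ssr + k * (sum(dat[i, ]) / k - grand)^2
  ssc <- 0
  for (j in seq_len(k)) ssc <- ssc + n * (sum(dat[, j]) / n - grand)^2
  sse <- 0
  for (i in seq_len(n)) for (j in seq_len(k)) {
    sse <- sse + (dat[i, j] - sum(dat[i, ]) / k - sum(dat[, j]) / n + grand)^2
  }
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  unname((msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse)))
}

naive_bland_altman <- function(a, b) {
  n <- length(a)
  d <- numeric(n)
  for (i in seq_len(n)) d[i] <- a[i] - b[i]
  bias <- sum(d) / n
  ss <- 0
  for (v in d) ss <- ss + (v - bias)^2
  s <- sqrt(ss / (n - 1))
  list(bias = bias, loa = c(bias - 1.96 * s, bias + 1.96 * s),
       cv_pct = 100 * s / (sum((a + b) / 2) / n))
}

# OLS slope/offset via the normal equations, accumulated by loop
naive_ols <- function(x, y) {
  n <- length(x)
  sx <- 0; sy <- 0; sxx <- 0; sxy <- 0
  for (i in seq_len(n)) {
    sx <- sx + x[i]; sy <- sy + y[i]
    sxx <- sxx + x[i]^2; sxy <- sxy + x[i] * y[i]
  }
  slope <- (n * sxy - sx * sy) / (n * sxx - sx^2)
  list(slope = slope, offset = (sy - slope * sx) / n)
}

# a random 3D rotation matrix (QR of a Gaussian matrix, det +1)
random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  q <- qr.Q(qr_)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

make_gyro <- function(n = 300, fs = 10, sd = 0.02) {
  gyro_trace(seq_len(n) / fs, rnorm(n, sd = sd), rnorm(n, sd = sd),
             rnorm(n, sd = sd), fs = fs)
}
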