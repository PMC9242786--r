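test_that("the 11-20 s window of a 30 s, 10 Hz trace has exactly 90 samples", {
  tr <- gyro_trace(seq(0.1, 30, by = 0.1), rep(0, 300), rep(0, 300),
                   rep(0, 300), fs = 10)
  w <- extract_window(tr)
  expect_equal(nrow(w), 90L)
  expect_true(all(w$t > 11 & w$t <= 20 + 1e-9))
})

test_that("windowing is idempotent and rejects short traces", {
  tt <- seq(11.1, 20, by = 0.1)
  tr <- gyro_trace(tt, rnorm(90), rnorm(90), rnorm(90), fs = 10)
  w <- extract_window(tr)
  expect_equal(w$gx, tr$gx)
  expect_equal(w$t, tr$t)

  short <- gyro_trace(seq(0.1, 15, by = 0.1), rnorm(150), rnorm(150),
                      rnorm(150), fs = 10)
  expect_error(extract_window(short), "insufficient duration")
})

test_that("magnitude series is the per-sample Euclidean norm", {
  tr <- gyro_trace(c(0.1, 0.2, 0.3), c(1, 0, 3), c(2, 0, 4), c(2, 0, 0),
                   fs = 10)
  expect_equal(as.numeric(magnitude_series(tr)), c(3, 0, 5))
})

test_that("metric closed forms hold on constant and tiny series", {
  const <- structure(rep(5, 90), fs = 10, class = "magnitude_series")
  expect_equal(compute_rms(const), 5)
  expect_equal(compute_range(const), 0)
  expect_equal(compute_ac(const), 45)
  expect_equal(compute_sd(const), 0)

  expect_equal(compute_rms(c(3, 4)), sqrt(12.5))
  expect_equal(compute_range(c(1, 3, 2)), 2)
  expect_equal(compute_ac(c(1, 2, 3), fs = 10), 0.6)
  expect_equal(compute_sd(c(1, 3, 2)), 3)

  expect_error(compute_rms(numeric(0)), "empty")
  expect_error(compute_sd(5), "at least 2")
})

test_that("compute_metrics composes window, magnitude and the four metrics", {
  n <- 300
  tr <- gyro_trace(seq_len(n) / 10, rep(3, n), rep(4, n), rep(0, n), fs = 10)
  m <- compute_metrics(tr)
  expect_equal(unlist(m), c(rms = 5, range = 0, ac = 45, sd = 0))

  zero <- gyro_trace(seq_len(n) / 10, rep(0, n), rep(0, n), rep(0, n),
                     fs = 10)
  expect_equal(unlist(compute_metrics(zero)),
               c(rms = 0, range = 0, ac = 0, sd = 0))
})

test_that("metrics ignore samples outside the analysis window", {
  set.seed(11)
  tr <- make_gyro()
  m0 <- compute_metrics(tr)
  out <- tr$t <= 11 + 1e-9 | tr$t > 20 + 1e-9
  tr2 <- gyro_trace(tr$t,
                    replace(tr$gx, out, rnorm(sum(out), sd = 5)),
                    replace(tr$gy, out, rnorm(sum(out), sd = 5)),
                    replace(tr$gz, out, rnorm(sum(out), sd = 5)), fs = 10)
  expect_identical(compute_metrics(tr2), m0)
})

test_that("metrics are scale-equivariant and rotation-invariant", {
  set.seed(21)
  for (rep in 1:20) {
    tr <- make_gyro(n = 250)
    m <- compute_metrics(tr)
    cc <- runif(1, 0.1, 10)
    scaled <- gyro_trace(tr$t, cc * tr$gx, cc * tr$gy, cc * tr$gz, fs = 10)
    expect_equal(unlist(compute_metrics(scaled)), cc * unlist(m),
                 tolerance = 1e-12)

    rot <- random_rotation()
    g <- t(rot %*% rbind(tr$gx, tr$gy, tr$gz))
    rotated <- gyro_trace(tr$t, g[, 1], g[, 2], g[, 3], fs = 10)
    expect_equal(unlist(compute_metrics(rotated)), unlist(m),
                 tolerance = 1e-12)
  }
})

test_that("summed distance dominates range, with equality on monotone series", {
  set.seed(31)
  for (rep in 1:50) {
    mg <- abs(rnorm(50))
    expect_gte(compute_sd(mg) + 1e-12, compute_range(mg))
    mono <- sort(mg)
    expect_equal(compute_sd(mono), compute_range(mono))
  }
})

test_that("COP path length handles tiny geometries", {
  expect_equal(cop_path_length(cop_trace(c(0, 1), c(0, 3), c(0, 4))), 5)
  expect_equal(cop_path_length(cop_trace(c(0, 1, 2), c(0, 1, 1),
                                         c(0, 0, 1))), 2)
  expect_equal(cop_path_length(cop_trace(0, 7, -2)), 0)
})

test_that("COP path is additive over concatenation and rotation-invariant", {
  set.seed(41)
  for (rep in 1:20) {
    n <- 60
    x <- cumsum(rnorm(n)); y <- cumsum(rnorm(n)); tt <- seq_len(n) / 10
    whole <- cop_path_length(cop_trace(tt, x, y))
    cut <- 25
    left <- cop_path_length(cop_trace(tt[1:cut], x[1:cut], y[1:cut]))
    right <- cop_path_length(cop_trace(tt[cut:n], x[cut:n], y[cut:n]))
    expect_equal(left + right, whole, tolerance = 1e-12)

    ang <- runif(1, 0, 2 * pi)
    xr <- cos(ang) * x - sin(ang) * y
    yr <- sin(ang) * x + cos(ang) * y
    expect_equal(cop_path_length(cop_trace(tt, xr, yr)), whole,
                 tolerance = 1e-12)
  }
})

test_that("trace containers reject malformed input", {
  expect_error(gyro_trace(c(0.1, 0.25, 0.3), 1:3, 1:3, 1:3, fs = 10),
               "non-uniform")
  expect_error(gyro_trace(c(0.2, 0.1), 1:2, 1:2, 1:2, fs = 10),
               "increasing")
  expect_error(gyro_trace(0.1, NA, 0, 0, fs = 10), "non-finite")
  expect_error(cop_trace(c(0, 1), c(1, Inf), c(0, 0)), "non-finite")
  expect_error(cop_trace(numeric(0), numeric(0), numeric(0)), "empty")
})
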