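#' Spearman rank correlation with t-based p-value
#'
#' Pearson correlation of mid-ranks (ties receive average ranks), with a
#' two-sided p-value from `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2`
#' degrees of freedom; `rho = +/-1` gives `p = 0`. Used for concurrent
#' validity because sway-metric distributions are non-normal.
#'
#' @param x,y equal-length numeric vectors, `n >= 3`, finite, non-constant.
#' @return A list with `rho`, `p_value` and `n`.
#' @examples
#' spearman_rho(1:10, (1:10)^3)$rho # 1: invariant to monotone transforms
#' @export
spearman_rho <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("`x` and `y` must have equal length", call. = FALSE)
  if (n < 3L) stop("need at least 3 pairs", call. = FALSE)
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("inputs must be finite", call. = FALSE)
  }
  if (var(x) == 0 || var(y) == 0) {
    stop("undefined correlation: constant input vector", call. = FALSE)
  }
  rx <- rank(x)
  ry <- rank(y)
  rho <- stats::cor(rx, ry)
  p <- if (abs(rho) >= 1 - 1e-15) {
    0
  } else {
    tval <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * pt(-abs(tval), df = n - 2)
  }
  list(rho = rho, p_value = p, n = n)
}

#' Intraclass correlation ICC(2,1), absolute agreement, with 95% CI
#'
#' Single-measure absolute-agreement ICC from the two-way random-effects
#' ANOVA decomposition of an `n` targets x 2 raters layout:
#' `ICC = (MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE))` with `k = 2`
#' raters, where MSR, MSC, MSE are the rows (targets), columns (raters) and
#' residual mean squares. The confidence interval is the F-based interval of
#' McGraw & Wong. Absolute agreement penalizes systematic offsets between
#' methods, which consistency-type ICCs and Pearson correlation do not.
#'
#' @param method_a,method_b equal-length numeric vectors (`n >= 5`), one
#'   measurement per target from each method.
#' @param alpha confidence level is `1 - alpha` (default 0.05).
#' @return A list with `icc`, `ci` (length-2 vector), `n`.
#' @examples
#' icc_2_1(1:20, 1:20)$icc # 1
#' @export
icc_2_1 <- function(method_a, method_b, alpha = 0.05) {
  n <- length(method_a)
  if (length(method_b) != n) {
    stop("method vectors must have equal length", call. = FALSE)
  }
  if (n < 5L) stop("need at least 5 paired measurements", call. = FALSE)
  if (!all(is.finite(method_a)) || !all(is.finite(method_b))) {
    stop("inputs must be finite", call. = FALSE)
  }
  k <- 2
  dat <- cbind(method_a, method_b)
  if (var(as.vector(dat)) == 0) {
    stop("undefined ICC: zero total variance", call. = FALSE)
  }
  row_means <- rowMeans(dat)
  col_means <- colMeans(dat)
  grand <- mean(dat)
  ssr <- k * sum((row_means - grand)^2)
  ssc <- n * sum((col_means - grand)^2)
  sst <- sum((dat - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
  if (icc >= 1 - 1e-12) {
    # perfect agreement: no residual or rater variance, interval degenerates
    return(list(icc = icc, ci = c(1, 1), n = n))
  }

  # McGraw & Wong F-based interval for the single-measure agreement ICC
  a <- (k * icc) / (n * (1 - icc))
  b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  fl <- qf(1 - alpha / 2, n - 1, v)
  fu <- qf(1 - alpha / 2, v, n - 1)
  lower <- n * (msr - fl * mse) /
    (fl * (k * msc + (k * n - k - n) * mse) + n * msr)
  upper <- n * (fu * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * fu * msr)
  list(icc = icc, ci = c(lower, upper), n = n)
}

#' Bland-Altman agreement: bias, limits of agreement, CV%
#'
#' For paired measurements the differences `d = a - b` give
#' `bias = mean(d)` and limits of agreement `bias +/- 1.96 * sd(d)` (sample
#' sd, `n - 1` denominator), the interval expected to contain ~95% of
#' between-method differences. The coefficient of variation is
#' `100 * sd(d) / mean((a + b) / 2)`; it is `NA` (with a warning) when the
#' grand mean of paired averages is zero.
#'
#' @param method_a,method_b equal-length numeric vectors, `n >= 2`.
#' @return A list with `bias`, `loa` (lower, upper), `cv_pct`, `n`.
#' @examples
#' bland_altman(c(10, 12, 14), c(11, 11, 15))
#' @export
bland_altman <- function(method_a, method_b) {
  n <- length(method_a)
  if (length(method_b) != n) {
    stop("method vectors must have equal length", call. = FALSE)
  }
  if (n < 2L) stop("need at least 2 pairs", call. = FALSE)
  d <- method_a - method_b
  bias <- mean(d)
  s <- sd(d)
  loa <- c(bias - 1.96 * s, bias + 1.96 * s)
  grand <- mean((method_a + method_b) / 2)
  cv <- if (grand == 0) {
    warning("CV% undefined: zero mean of paired averages")
    NA_real_
  } else {
    100 * s / grand
  }
  list(bias = bias, loa = loa, cv_pct = cv, n = n)
}

#' Slope and offset of predicted vs actual
#'
#' Ordinary least squares of `predicted = m * actual + c`. For a
#' well-calibrated prediction model the slope `m` is close to 1 and the
#' offset `c` close to 0; among competing models the one whose slope is
#' closest to 1 with the smallest offset is preferred.
#'
#' @param actual reference measurements (regressor); must have variance > 0.
#' @param predicted model output (response), same length.
#' @return A list with `slope`, `offset`.
#' @examples
#' linear_agreement(1:10, 2 * (1:10) + 3) # slope 2, offset 3
#' @export
linear_agreement <- function(actual, predicted) {
  n <- length(actual)
  if (length(predicted) != n) {
    stop("vectors must have equal length", call. = FALSE)
  }
  if (n < 2L) stop("need at least 2 pairs", call. = FALSE)
  if (var(actual) == 0) {
    stop("undefined fit: `actual` has zero variance", call. = FALSE)
  }
  fit <- lm(predicted ~ actual)
  list(slope = unname(coef(fit)[2L]), offset = unname(coef(fit)[1L]))
}

#' Full agreement report for two paired measurement vectors
#'
#' Bundles every validity/agreement statistic used to compare a candidate
#' measurement against a reference: Spearman's rho with p, ICC(2,1) with
#' 95% CI, Bland-Altman bias / limits of agreement / CV%, and the OLS
#' slope and offset of `candidate` on `reference`.
#'
#' @param reference gold-standard measurements (e.g. force-plate COP path,
#'   mm).
#' @param candidate paired candidate measurements (e.g. model predictions).
#' @return A list of class `agreement_report` with fields `rho`, `p_value`,
#'   `icc`, `icc_ci95`, `bias`, `loa`, `cv_pct`, `slope`, `offset`, `n`.
#' @export
agreement_report <- function(reference, candidate) {
  sp <- spearman_rho(reference, candidate)
  ic <- icc_2_1(reference, candidate)
  ba <- bland_altman(candidate, reference)
  la <- linear_agreement(reference, candidate)
  structure(list(rho = sp$rho, p_value = sp$p_value,
                 icc = ic$icc, icc_ci95 = ic$ci,
                 bias = ba$bias, loa = ba$loa, cv_pct = ba$cv_pct,
                 slope = la$slope, offset = la$offset, n = sp$n),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf(
    paste0("<agreement_report> n=%d\n",
           "  Spearman rho %.3f (p=%.3g)\n",
           "  ICC(2,1) %.3f [%.3f, %.3f]\n",
           "  bias %.2f, LoA [%.2f, %.2f], CV %.1f%%\n",
           "  slope %.3f, offset %.2f\n"),
    x$n, x$rho, x$p_value, x$icc, x$icc_ci95[1], x$icc_ci95[2],
    x$bias, x$loa[1], x$loa[2], x$cv_pct, x$slope, x$offset))
  invisible(x)
}

#' Concurrent-validity table: sway metrics vs COP path
#'
#' One row per gyroscope sway metric (RMS, Range, AC, SD) giving its
#' Spearman correlation and p-value against the force-plate COP path
#' length, pooled over all trials.
#'
#' @param features a [feature_table()] (columns `rms`, `range`, `ac`, `sd`,
#'   `cop_path_mm`), or a data frame with those columns.
#' @return A data frame with columns `metric`, `rho`, `p_value`.
#' @export
validity_table <- function(features) {
  if (nrow(features) < 5L) stop("need at least 5 trials", call. = FALSE)
  metrics <- c("rms", "range", "ac", "sd")
  rows <- lapply(metrics, function(m) {
    sp <- spearman_rho(features[[m]], features$cop_path_mm)
    data.frame(metric = m, rho = sp$rho, p_value = sp$p_value,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
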