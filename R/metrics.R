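#' Extract the steady-state analysis window from a gyroscope trace
#'
#' Quiet-stance recordings show adaptation at the start of a trial and
#' fatigue or anticipation at the end, so sway metrics are computed on a
#' mid-trial window. Samples with timestamps in the half-open interval
#' `(start_s, end_s]` are kept; at 10 Hz with `t = n/10` the default 11-20 s
#' window contains exactly 90 samples. A trace that does not span the window
#' is an error, never silently truncated.
#'
#' @param trace a [gyro_trace()].
#' @param start_s,end_s window bounds in seconds (defaults 11 and 20).
#' @return A [gyro_trace()] restricted to the window.
#' @examples
#' tr <- gyro_trace(seq(0.1, 30, by = 0.1), rnorm(300, sd = 0.01),
#'                  rnorm(300, sd = 0.01), rnorm(300, sd = 0.01), fs = 10)
#' nrow(extract_window(tr)) # 90
#' @export
extract_window <- function(trace, start_s = 11, end_s = 20) {
  stopifnot(inherits(trace, "gyro_trace"))
  if (end_s <= start_s) stop("`end_s` must exceed `start_s`", call. = FALSE)
  if (max(trace$t) < end_s - 1e-9) {
    stop(sprintf(
      "insufficient duration: trace ends at %.2f s but the window needs %.2f s",
      max(trace$t), end_s), call. = FALSE)
  }
  keep <- trace$t > start_s + 1e-9 & trace$t <= end_s + 1e-9
  gyro_trace(trace$t[keep], trace$gx[keep], trace$gy[keep], trace$gz[keep],
             fs = attr(trace, "fs"))
}

#' Gyroscope magnitude series
#'
#' The per-sample Euclidean norm of the triaxial angular-velocity vector,
#' `MG(n) = sqrt(gx(n)^2 + gy(n)^2 + gz(n)^2)`. The norm is invariant to any
#' rigid rotation of the sensor axes, which is what makes magnitude-based
#' sway metrics insensitive to sensor placement.
#'
#' @param trace a [gyro_trace()].
#' @return An object of class `magnitude_series`: a numeric vector `mg`
#'   (rad/s) with attribute `fs`.
#' @export
magnitude_series <- function(trace) {
  stopifnot(inherits(trace, "gyro_trace"))
  mg <- sqrt(trace$gx^2 + trace$gy^2 + trace$gz^2)
  structure(mg, fs = attr(trace, "fs"), class = "magnitude_series")
}

as_mg <- function(mg) {
  if (inherits(mg, "magnitude_series")) return(mg)
  if (!is.numeric(mg)) stop("`mg` must be numeric", call. = FALSE)
  structure(as.numeric(mg), fs = attr(mg, "fs"), class = "magnitude_series")
}

#' Windowed sway metrics of the gyroscope magnitude series
#'
#' The four amplitude metrics used to quantify trunk sway from a magnitude
#' series `MG(n)` of `N` samples:
#'
#' * `compute_rms()`: root-mean-square, `sqrt(sum(MG^2) / N)` (rad/s).
#' * `compute_range()`: `max(MG) - min(MG)` (rad/s).
#' * `compute_ac()`: rectangle-rule area under the curve,
#'   `(1/fs) * sum(MG)` (rad). At the native 10 Hz rate the multiplier is
#'   1/10; it generalizes to `1/fs` so the units stay rad at any rate.
#' * `compute_sd()`: summed absolute successive differences (total
#'   variation), `sum(|MG(n) - MG(n-1)|)` (rad/s).
#'
#' All four scale linearly with the signal amplitude and are non-negative.
#'
#' @param mg a `magnitude_series` (or bare numeric vector for `compute_rms`,
#'   `compute_range` and `compute_sd`; `compute_ac` needs `fs`).
#' @param fs sampling rate in Hz; defaults to the `fs` attribute of `mg`.
#' @return A single non-negative number.
#' @name sway_metric_ops
NULL

#' @rdname sway_metric_ops
#' @export
compute_rms <- function(mg) {
  mg <- as_mg(mg)
  if (length(mg) == 0L) stop("empty magnitude series", call. = FALSE)
  sqrt(sum(mg^2) / length(mg))
}

#' @rdname sway_metric_ops
#' @export
compute_range <- function(mg) {
  mg <- as_mg(mg)
  if (length(mg) == 0L) stop("empty magnitude series", call. = FALSE)
  max(mg) - min(mg)
}

#' @rdname sway_metric_ops
#' @export
compute_ac <- function(mg, fs = attr(mg, "fs")) {
  mg <- as_mg(mg)
  if (length(mg) == 0L) stop("empty magnitude series", call. = FALSE)
  if (is.null(fs)) stop("`fs` required for the area under the curve",
                        call. = FALSE)
  stopifnot_scalar_pos(fs, "fs")
  sum(mg) / fs
}

#' @rdname sway_metric_ops
#' @export
compute_sd <- function(mg) {
  mg <- as_mg(mg)
  if (length(mg) < 2L) {
    stop("summed distance needs at least 2 samples", call. = FALSE)
  }
  sum(abs(diff(mg)))
}

#' All four sway metrics of a gyroscope trace
#'
#' Convenience composition: window the trace (default 11-20 s), take the
#' magnitude series, and compute RMS, Range, AC and SD.
#'
#' @inheritParams extract_window
#' @return A one-row data frame with columns `rms`, `range`, `ac`, `sd`.
#' @examples
#' tt <- seq(0.1, 30, by = 0.1)
#' tr <- gyro_trace(tt, rep(3, 300), rep(4, 300), rep(0, 300), fs = 10)
#' compute_metrics(tr) # rms 5, range 0, ac 45, sd 0
#' @export
compute_metrics <- function(trace, start_s = 11, end_s = 20) {
  mg <- magnitude_series(extract_window(trace, start_s, end_s))
  data.frame(rms = compute_rms(mg), range = compute_range(mg),
             ac = compute_ac(mg), sd = compute_sd(mg))
}

#' Center-of-pressure path length
#'
#' Total length of the COP trajectory across both the mediolateral and
#' anteroposterior directions: the sum of Euclidean distances between
#' successive samples, `sum(sqrt(dx^2 + dy^2))` in mm. A single-sample trace
#' has path length 0.
#'
#' @param cop a [cop_trace()].
#' @return Path length in mm.
#' @examples
#' cop_path_length(cop_trace(c(0, 1), c(0, 3), c(0, 4))) # 5
#' @export
cop_path_length <- function(cop) {
  stopifnot(inherits(cop, "cop_trace"))
  if (nrow(cop) < 2L) return(0)
  sum(sqrt(diff(cop$x)^2 + diff(cop$y)^2))
}

# COP analogue of extract_window(); same (start_s, end_s] convention.
window_cop <- function(cop, start_s = 11, end_s = 20) {
  stopifnot(inherits(cop, "cop_trace"))
  if (max(cop$t) < end_s - 1e-9) {
    stop(sprintf(
      "insufficient duration: COP trace ends at %.2f s but the window needs %.2f s",
      max(cop$t), end_s), call. = FALSE)
  }
  keep <- cop$t > start_s + 1e-9 & cop$t <= end_s + 1e-9
  cop_trace(cop$t[keep], cop$x[keep], cop$y[keep])
}

#' Build the trial-by-metric feature table for COP-path prediction
#'
#' One row per trial with the four gyroscope sway metrics as predictors and
#' the force-plate COP path length (mm) as target. `windowing` controls the
#' interval over which the COP path target is measured: `"window"` (default)
#' uses the same 11-20 s window as the gyroscope metrics so both instruments
#' describe the same interval; `"full"` uses the whole captured trace.
#'
#' @param cohort a `sway_cohort` from [simulate_cohort()] (or any list of
#'   trial records with fields `subject_id`, `condition`, `gyro`, `cop`).
#' @param windowing `"window"` or `"full"` COP-path policy.
#' @param start_s,end_s analysis window bounds in seconds.
#' @return A data frame of class `feature_table` with columns `subject_id`,
#'   `condition`, `rms`, `range`, `ac`, `sd`, `cop_path_mm`.
#' @export
feature_table <- function(cohort, windowing = c("window", "full"),
                          start_s = 11, end_s = 20) {
  windowing <- match.arg(windowing)
  rows <- lapply(cohort, function(tr) {
    m <- compute_metrics(tr$gyro, start_s, end_s)
    target <- if (windowing == "window") {
      cop_path_length(window_cop(tr$cop, start_s, end_s))
    } else {
      cop_path_length(tr$cop)
    }
    cbind(data.frame(subject_id = tr$subject_id, condition = tr$condition,
                     stringsAsFactors = FALSE),
          m, cop_path_mm = target)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (anyNA(out) || !all(is.finite(out$cop_path_mm))) {
    stop("feature table contains missing or non-finite values", call. = FALSE)
  }
  class(out) <- c("feature_table", "data.frame")
  out
}
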