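#' Triaxial gyroscope trace
#'
#' Container for a uniformly sampled angular-velocity recording from a
#' trunk-worn triaxial gyroscope. Channels follow the sensor convention used
#' in posturography: `gx` = roll (mediolateral lean rate), `gy` = pitch
#' (anteroposterior lean rate), `gz` = yaw, all in rad/s.
#'
#' @param t numeric vector of timestamps in seconds, strictly increasing and
#'   uniformly spaced at `1/fs` (tolerance 1e-6 s).
#' @param gx,gy,gz numeric angular-velocity channels, rad/s, same length as
#'   `t`.
#' @param fs sampling rate in Hz.
#'
#' @return An object of class `gyro_trace`: a data frame with columns
#'   `t, gx, gy, gz` and attribute `fs`.
#' @examples
#' tr <- gyro_trace(t = seq(0.1, 3, by = 0.1),
#'                  gx = rnorm(30, sd = 0.01),
#'                  gy = rnorm(30, sd = 0.01),
#'                  gz = rnorm(30, sd = 0.01), fs = 10)
#' tr
#' @export
gyro_trace <- function(t, gx, gy, gz, fs) {
  stopifnot_scalar_pos(fs, "fs")
  n <- length(t)
  if (length(gx) != n || length(gy) != n || length(gz) != n) {
    stop("all gyroscope channels must have the same length as `t`",
         call. = FALSE)
  }
  if (n == 0L) stop("empty gyroscope trace", call. = FALSE)
  if (!all(is.finite(c(t, gx, gy, gz)))) {
    stop("gyroscope trace contains non-finite values", call. = FALSE)
  }
  if (n > 1L) {
    dt <- diff(t)
    if (any(dt <= 0)) stop("timestamps must be strictly increasing",
                           call. = FALSE)
    if (max(abs(dt - 1 / fs)) >= 1e-6) {
      stop("non-uniform sampling: timestamps must be spaced 1/fs apart",
           call. = FALSE)
    }
  }
  out <- data.frame(t = t, gx = gx, gy = gy, gz = gz)
  attr(out, "fs") <- fs
  class(out) <- c("gyro_trace", "data.frame")
  out
}

#' Planar center-of-pressure trace
#'
#' Container for a force-plate center-of-pressure (COP) trajectory during
#' quiet stance. `x` is the mediolateral coordinate, `y` the anteroposterior
#' coordinate, both in mm.
#'
#' @param t numeric timestamps in seconds, strictly increasing.
#' @param x,y numeric COP coordinates in mm, same length as `t`.
#'
#' @return An object of class `cop_trace`: a data frame with columns
#'   `t, x, y`.
#' @examples
#' cop_trace(t = c(0.1, 0.2, 0.3), x = c(0, 3, 3), y = c(0, 4, 5))
#' @export
cop_trace <- function(t, x, y) {
  n <- length(t)
  if (length(x) != n || length(y) != n) {
    stop("`x`, `y` and `t` must have equal length", call. = FALSE)
  }
  if (n == 0L) stop("empty COP trace", call. = FALSE)
  if (!all(is.finite(c(t, x, y)))) {
    stop("COP trace contains non-finite values", call. = FALSE)
  }
  if (n > 1L && any(diff(t) <= 0)) {
    stop("timestamps must be strictly increasing", call. = FALSE)
  }
  out <- data.frame(t = t, x = x, y = y)
  class(out) <- c("cop_trace", "data.frame")
  out
}

#' @export
print.gyro_trace <- function(x, ...) {
  cat(sprintf("<gyro_trace> %d samples @ %g Hz, %.1f-%.1f s\n",
              nrow(x), attr(x, "fs"), min(x$t), max(x$t)))
  invisible(x)
}

#' @export
print.cop_trace <- function(x, ...) {
  cat(sprintf("<cop_trace> %d samples, %.1f-%.1f s, path %.1f mm\n",
              nrow(x), min(x$t), max(x$t), cop_path_length(x)))
  invisible(x)
}

# Subsetting a trace data frame drops the class (plain data.frame comes back);
# windowing helpers rebuild the container explicitly instead.
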