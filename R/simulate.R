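#' Configuration for the paired-sway cohort simulator
#'
#' Describes a synthetic quiet-stance study: `n_subjects` participants each
#' tested in six stance/vision conditions of increasing difficulty
#' (double stance, tandem stance, single-leg stance, each with eyes open or
#' closed). Sway is modeled as a planar Ornstein-Uhlenbeck (OU) process for
#' the COP, with the trunk gyroscope derived through a small-angle inverted
#' pendulum.
#'
#' `base_intensity` is the OU diffusion scale per condition in
#' mm s^-1/2 and must be strictly increasing over the condition order:
#' harder stances sway more. The stationary per-axis COP standard deviation
#' is `intensity / sqrt(2 * ou_theta)` mm, so the defaults span roughly
#' 1.3 mm (double stance, eyes open) to 7 mm mediolateral (single leg, eyes
#' closed) — typical quiet-stance amplitudes.
#'
#' @param n_subjects number of participants (default 53).
#' @param conditions ordered character vector of condition codes.
#' @param duration_s trial length in seconds (default 30).
#' @param fs_gyro,fs_cop output sampling rates in Hz (default 10).
#' @param base_intensity named numeric vector, OU intensity per condition,
#'   mm s^-1/2, strictly increasing over `conditions`.
#' @param subject_sd between-subject dispersion of the log-normal
#'   susceptibility multiplier (log scale; default 0.35).
#' @param ou_theta OU mean-reversion rate, 1/s (default 0.5: ~2 s
#'   correlation time, the bounded, persistent character of quiet stance).
#' @param pendulum_length_mm effective center-of-mass height used to convert
#'   COP excursion to trunk angle (default 1000 mm).
#' @param gyro_noise_sd additive Gaussian sensor noise per gyro axis, rad/s
#'   (default 0.002).
#' @param seed integer RNG seed for the cohort.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 53,
                       conditions = c("ST-EO", "ST-EC", "TS-EO",
                                      "TS-EC", "SL-EO", "SL-EC"),
                       duration_s = 30,
                       fs_gyro = 10,
                       fs_cop = 10,
                       base_intensity = c("ST-EO" = 1.3, "ST-EC" = 1.8,
                                          "TS-EO" = 2.5, "TS-EC" = 3.5,
                                          "SL-EO" = 5.0, "SL-EC" = 7.0),
                       subject_sd = 0.35,
                       ou_theta = 0.5,
                       pendulum_length_mm = 1000,
                       gyro_noise_sd = 0.002,
                       seed = 1L) {
  stopifnot_scalar_pos(n_subjects, "n_subjects")
  stopifnot_scalar_pos(duration_s, "duration_s")
  stopifnot_scalar_pos(fs_gyro, "fs_gyro")
  stopifnot_scalar_pos(fs_cop, "fs_cop")
  stopifnot_scalar_pos(ou_theta, "ou_theta")
  stopifnot_scalar_pos(pendulum_length_mm, "pendulum_length_mm")
  if (gyro_noise_sd < 0) stop("`gyro_noise_sd` must be >= 0", call. = FALSE)
  if (subject_sd < 0) stop("`subject_sd` must be >= 0", call. = FALSE)
  if (is.null(names(base_intensity))) names(base_intensity) <- conditions
  base_intensity <- base_intensity[conditions]
  if (anyNA(base_intensity)) {
    stop("`base_intensity` must name every condition", call. = FALSE)
  }
  if (any(base_intensity <= 0) || any(diff(base_intensity) <= 0)) {
    stop(paste("`base_intensity` must be strictly positive and strictly",
               "increasing over the condition order"), call. = FALSE)
  }
  structure(list(n_subjects = as.integer(n_subjects), conditions = conditions,
                 duration_s = duration_s, fs_gyro = fs_gyro, fs_cop = fs_cop,
                 base_intensity = base_intensity, subject_sd = subject_sd,
                 ou_theta = ou_theta, pendulum_length_mm = pendulum_length_mm,
                 gyro_noise_sd = gyro_noise_sd, seed = as.integer(seed)),
            class = "sim_config")
}

# Both streams are simulated on a common fine grid and decimated, so the
# finite-difference gyro derivative is formed before any down-sampling.
INTERNAL_FS <- 50

#' Simulate a center-of-pressure trajectory
#'
#' Draws a planar discretized Ornstein-Uhlenbeck process starting at the
#' origin: `x[n+1] = x[n] - theta * x[n] * dt + intensity * sqrt(dt) * eps`,
#' with independent standard-normal innovations per axis. The
#' anteroposterior axis uses 1.5x the mediolateral intensity, reflecting the
#' anteroposterior dominance of quiet-stance sway. Simulation runs on an
#' internal 50 Hz grid and is decimated to `fs`.
#'
#' @param intensity mediolateral OU diffusion scale, mm s^-1/2 (>= 0; 0
#'   gives a trace pinned at the origin).
#' @param ou_theta mean-reversion rate, 1/s.
#' @param duration_s trial length, s.
#' @param fs output sampling rate, Hz.
#' @param ap_ratio anteroposterior / mediolateral intensity ratio.
#' @param internal_fs fine simulation grid, Hz (must be a multiple of `fs`).
#' @return A [cop_trace()] with timestamps `1/fs, 2/fs, ..., duration_s`.
#' @export
simulate_cop <- function(intensity, ou_theta, duration_s, fs,
                         ap_ratio = 1.5, internal_fs = INTERNAL_FS) {
  if (intensity < 0) stop("`intensity` must be >= 0", call. = FALSE)
  stopifnot_scalar_pos(ou_theta, "ou_theta")
  stopifnot_scalar_pos(duration_s, "duration_s")
  stopifnot_scalar_pos(fs, "fs")
  if (internal_fs < fs || abs(internal_fs / fs - round(internal_fs / fs)) > 1e-9) {
    stop("`internal_fs` must be a multiple of `fs`", call. = FALSE)
  }
  dt <- 1 / internal_fs
  n <- round(duration_s * internal_fs)
  x <- numeric(n + 1L)
  y <- numeric(n + 1L)
  ex <- rnorm(n)
  ey <- rnorm(n)
  sx <- intensity * sqrt(dt)
  sy <- ap_ratio * intensity * sqrt(dt)
  for (i in seq_len(n)) {
    x[i + 1L] <- x[i] - ou_theta * x[i] * dt + sx * ex[i]
    y[i + 1L] <- y[i] - ou_theta * y[i] * dt + sy * ey[i]
  }
  tt <- (0:n) * dt
  # keep samples on the n/fs grid, dropping t = 0 so traces start at 1/fs
  keep <- which(abs(tt * fs - round(tt * fs)) < 1e-9 & tt > 0)
  cop_trace(tt[keep], x[keep], y[keep])
}

#' Derive a trunk gyroscope trace from a COP trajectory
#'
#' Small-angle inverted-pendulum link between the COP and trunk motion: the
#' lean angle per axis is `theta(t) = cop(t) / pendulum_length_mm`, and the
#' gyroscope reads its finite-difference derivative. The anteroposterior COP
#' axis maps to pitch (`gy`), the mediolateral axis to roll (`gx`); yaw
#' (`gz`) carries no sway signal. Independent Gaussian sensor noise of sd
#' `gyro_noise_sd` is added to all three axes, and the result is decimated
#' to `fs_out` (the input rate must be a multiple of `fs_out`).
#'
#' @param cop a [cop_trace()] with at least 2 uniformly spaced samples.
#' @param pendulum_length_mm effective COM height, mm.
#' @param gyro_noise_sd per-axis sensor noise sd, rad/s.
#' @param fs_out output rate, Hz; defaults to the COP rate.
#' @return A [gyro_trace()].
#' @export
derive_gyro <- function(cop, pendulum_length_mm, gyro_noise_sd = 0,
                        fs_out = NULL) {
  stopifnot(inherits(cop, "cop_trace"))
  if (nrow(cop) < 2L) {
    stop("insufficient data: COP trace needs at least 2 samples",
         call. = FALSE)
  }
  stopifnot_scalar_pos(pendulum_length_mm, "pendulum_length_mm")
  dts <- diff(cop$t)
  dt <- dts[1L]
  if (max(abs(dts - dt)) >= 1e-6) {
    stop("COP trace must be uniformly sampled to derive angular velocity",
         call. = FALSE)
  }
  fs_in <- 1 / dt
  if (is.null(fs_out)) fs_out <- fs_in
  roll <- diff(cop$x / pendulum_length_mm) / dt
  pitch <- diff(cop$y / pendulum_length_mm) / dt
  tt <- cop$t[-1L]
  m <- length(tt)
  gx <- roll + rnorm(m, sd = gyro_noise_sd)
  gy <- pitch + rnorm(m, sd = gyro_noise_sd)
  gz <- rnorm(m, sd = gyro_noise_sd)
  if (abs(fs_in / fs_out - round(fs_in / fs_out)) > 1e-9 || fs_out > fs_in) {
    stop("input rate must be a multiple of `fs_out`", call. = FALSE)
  }
  # keep samples landing on the n/fs_out grid so window counts are exact
  keep <- which(abs(tt * fs_out - round(tt * fs_out)) < 1e-9)
  gyro_trace(tt[keep], gx[keep], gy[keep], gz[keep], fs = fs_out)
}

#' Simulate a paired gyroscope/COP cohort
#'
#' Generates `n_subjects` x `length(conditions)` trial records. Each subject
#' draws a log-normal susceptibility multiplier `exp(u)`,
#' `u ~ N(0, subject_sd^2)`, shared across that subject's conditions; the
#' per-trial OU intensity is `base_intensity[condition] * exp(u)`. Per-trial
#' RNG substreams are derived deterministically from the cohort seed and the
#' (subject, condition) index, so the cohort is reproducible and insensitive
#' to generation order. The caller's RNG state is left untouched.
#'
#' Each trial record is a list with `subject_id`, `condition`, `gyro`
#' ([gyro_trace()]), `cop` ([cop_trace()]) and `cop_path_mm`, the path
#' length of the full stored COP trace.
#'
#' @param config a [sim_config()].
#' @return A list of trial records, class `sway_cohort`.
#' @examples
#' cohort <- simulate_cohort(sim_config(n_subjects = 2, seed = 7))
#' length(cohort) # 12
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  subj_mult <- with_seed(config$seed,
                         exp(rnorm(config$n_subjects, sd = config$subject_sd)))
  records <- vector("list", config$n_subjects * length(config$conditions))
  idx <- 0L
  for (s in seq_len(config$n_subjects)) {
    for (ci in seq_along(config$conditions)) {
      cond <- config$conditions[ci]
      idx <- idx + 1L
      records[[idx]] <- with_seed(trial_seed(config$seed, s, ci), {
        hi_cop <- simulate_cop(config$base_intensity[[cond]] * subj_mult[s],
                               config$ou_theta, config$duration_s,
                               fs = INTERNAL_FS, internal_fs = INTERNAL_FS)
        gyro <- derive_gyro(hi_cop, config$pendulum_length_mm,
                            config$gyro_noise_sd, fs_out = config$fs_gyro)
        keep <- which(abs(hi_cop$t * config$fs_cop -
                            round(hi_cop$t * config$fs_cop)) < 1e-9)
        cop <- cop_trace(hi_cop$t[keep], hi_cop$x[keep], hi_cop$y[keep])
        list(subject_id = sprintf("S%02d", s), condition = cond,
             gyro = gyro, cop = cop, cop_path_mm = cop_path_length(cop))
      })
    }
  }
  structure(records, class = "sway_cohort",
            config = config)
}

#' @export
print.sway_cohort <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("<sway_cohort> %d trials (%d subjects x %d conditions), %g s @ %g Hz\n",
              length(x), cfg$n_subjects, length(cfg$conditions),
              cfg$duration_s, cfg$fs_gyro))
  invisible(x)
}

#' Write / read a cohort as per-trial CSV files plus a manifest
#'
#' `write_cohort()` writes one gyro CSV (`t_s,gx_rads,gy_rads,gz_rads`) and
#' one COP CSV (`t_s,cop_x_mm,cop_y_mm`) per trial, plus a manifest
#' `manifest.csv` with columns
#' `subject_id,condition,gyro_file,cop_file,cop_path_mm`. `read_cohort()`
#' reads such a directory back into a `sway_cohort`.
#'
#' @param cohort a `sway_cohort`.
#' @param dir output directory (created if missing).
#' @param fs_gyro gyroscope sampling rate assumed when reading back.
#' @return `write_cohort()` the manifest path, invisibly; `read_cohort()` a
#'   `sway_cohort`.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- do.call(rbind, lapply(seq_along(cohort), function(i) {
    tr <- cohort[[i]]
    gf <- sprintf("%s_%s_gyro.csv", tr$subject_id, tr$condition)
    cf <- sprintf("%s_%s_cop.csv", tr$subject_id, tr$condition)
    write.csv(data.frame(t_s = tr$gyro$t, gx_rads = tr$gyro$gx,
                         gy_rads = tr$gyro$gy, gz_rads = tr$gyro$gz),
              file.path(dir, gf), row.names = FALSE)
    write.csv(data.frame(t_s = tr$cop$t, cop_x_mm = tr$cop$x,
                         cop_y_mm = tr$cop$y),
              file.path(dir, cf), row.names = FALSE)
    data.frame(subject_id = tr$subject_id, condition = tr$condition,
               gyro_file = gf, cop_file = cf, cop_path_mm = tr$cop_path_mm,
               stringsAsFactors = FALSE)
  }))
  path <- file.path(dir, "manifest.csv")
  write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir, fs_gyro = 10) {
  manifest <- read.csv(file.path(dir, "manifest.csv"),
                       stringsAsFactors = FALSE)
  records <- lapply(seq_len(nrow(manifest)), function(i) {
    g <- read.csv(file.path(dir, manifest$gyro_file[i]))
    cp <- read.csv(file.path(dir, manifest$cop_file[i]))
    list(subject_id = manifest$subject_id[i],
         condition = manifest$condition[i],
         gyro = gyro_trace(g$t_s, g$gx_rads, g$gy_rads, g$gz_rads,
                           fs = fs_gyro),
         cop = cop_trace(cp$t_s, cp$cop_x_mm, cp$cop_y_mm),
         cop_path_mm = manifest$cop_path_mm[i])
  })
  structure(records, class = "sway_cohort", config = NULL)
}
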