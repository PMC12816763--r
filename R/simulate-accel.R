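#' Construct a triaxial accelerometer stream
#'
#' Regularly sampled triaxial acceleration in g. Timestamps are implicit
#' (`start_time + i / sample_rate`) to keep multi-day 100 Hz streams
#' compact.
#'
#' @param ax,ay,az Acceleration per axis (g), equal lengths.
#' @param sample_rate Sampling frequency (Hz); the device default is 100.
#' @param start_time POSIXct start of the stream.
#' @return An object of class `accel_stream`.
#' @export
accel_stream <- function(ax, ay, az, sample_rate = 100,
                         start_time = as.POSIXct("2026-01-05 00:00:00",
                                                 tz = "UTC")) {
  stopifnot(length(ax) == length(ay), length(ay) == length(az),
            sample_rate > 0)
  structure(
    list(ax = ax, ay = ay, az = az, n = length(ax),
         sample_rate = sample_rate, start_time = start_time),
    class = "accel_stream"
  )
}

#' @export
print.accel_stream <- function(x, ...) {
  cat(sprintf("<accel_stream> %d samples @ %g Hz (%.2f h) from %s\n",
              x$n, x$sample_rate, x$n / x$sample_rate / 3600,
              format(x$start_time)))
  invisible(x)
}

#' Seconds since stream start for each sample
#' @param stream An `accel_stream`.
#' @return Numeric vector of offsets (s).
#' @export
stream_seconds <- function(stream) {
  (seq_len(stream$n) - 1) / stream$sample_rate
}

#' Simulate a free-living accelerometer stream with known ground truth
#'
#' Generates a triaxial stream starting at local midnight. Worn time is
#' gravity plus small postural noise; walking bouts are sinusoidal
#' oscillations at a fixed step cadence (one vertical-axis cycle per step)
#' with smaller out-of-phase components on the horizontal axes; nonwear
#' blocks are an exactly constant 1-g gravity vector. Ground-truth steps per
#' day and the noise-free per-epoch activity counts implied by the count
#' definition (band-limited rectified integral, 1 count = 0.1 g s) are
#' recorded alongside.
#'
#' @param days Number of whole 24-h days (>= 1).
#' @param bouts_per_day Number of walking bouts per day; defaults start on
#'   the hour from 09:00, every 2 h.
#' @param nonwear_blocks List of `c(start_s, duration_s)` nonwear intervals
#'   (seconds since stream start); must not overlap.
#' @param seed Integer seed for the postural noise.
#' @param sample_rate Sampling frequency (Hz); default 100.
#' @param steps_per_bout Steps in each bout (default 600).
#' @param cadence_spm Step cadence (steps per minute, default 100).
#' @param bout_amplitude Vertical-axis oscillation amplitude (g).
#' @param posture_sd Postural noise sd while worn (g, default 0.02).
#' @param bout_starts_s Optional explicit bout start times (seconds since
#'   stream start, recycled across days not applied — absolute).
#'
#' @return An `accel_stream` with a `truth` component: `steps_by_day`
#'   (date, steps), `epoch_vmu` (epoch_start, vmu), `nonwear_blocks`.
#' @export
simulate_accel_stream <- function(days = 1, bouts_per_day = 2,
                                  nonwear_blocks = NULL, seed = 1L,
                                  sample_rate = 100,
                                  steps_per_bout = 600, cadence_spm = 100,
                                  bout_amplitude = 0.4, posture_sd = 0.02,
                                  bout_starts_s = NULL) {
  stopifnot(days >= 1, bouts_per_day >= 0)
  fs <- sample_rate
  n <- as.integer(round(days * 86400 * fs))
  tsec <- (seq_len(n) - 1) / fs

  if (!is.null(nonwear_blocks) && length(nonwear_blocks)) {
    nb <- do.call(rbind, lapply(nonwear_blocks, function(b) b[1:2]))
    nb <- nb[order(nb[, 1]), , drop = FALSE]
    if (nrow(nb) > 1 &&
        any(nb[-nrow(nb), 1] + nb[-nrow(nb), 2] > nb[-1, 1] + 1e-9)) {
      stop("nonwear blocks overlap")
    }
  }

  noise <- withr_seed(seed, function() {
    matrix(stats::rnorm(3 * n, 0, posture_sd), ncol = 3)
  })
  ax <- noise[, 1]
  ay <- noise[, 2]
  az <- 1 + noise[, 3]

  # walking bouts
  step_hz <- cadence_spm / 60
  bout_dur <- steps_per_bout / step_hz
  if (is.null(bout_starts_s)) {
    if (bouts_per_day > 0) {
      per_day <- 9 * 3600 + (seq_len(bouts_per_day) - 1) * 7200
      bout_starts_s <- as.vector(outer(per_day, (seq_len(days) - 1) * 86400,
                                       "+"))
    } else {
      bout_starts_s <- numeric(0)
    }
  }
  for (b0 in bout_starts_s) {
    idx <- which(tsec >= b0 & tsec < b0 + bout_dur)
    if (!length(idx)) next
    ph <- 2 * pi * step_hz * (tsec[idx] - b0)
    az[idx] <- az[idx] + bout_amplitude * sin(ph)
    ax[idx] <- ax[idx] + 0.4 * bout_amplitude * sin(ph + pi / 3)
    ay[idx] <- ay[idx] + 0.3 * bout_amplitude * cos(ph)
  }

  # nonwear: exactly constant gravity vector
  if (!is.null(nonwear_blocks)) {
    for (b in nonwear_blocks) {
      idx <- which(tsec >= b[1] & tsec < b[1] + b[2])
      ax[idx] <- 0
      ay[idx] <- 0
      az[idx] <- 1
    }
  }

  stream <- accel_stream(ax, ay, az, sample_rate = fs)

  # ground truth ------------------------------------------------------
  in_nonwear <- function(s) {
    if (is.null(nonwear_blocks)) return(FALSE)
    any(vapply(nonwear_blocks,
               function(b) s >= b[1] && s < b[1] + b[2], logical(1)))
  }
  dates <- as.Date(stream$start_time) + (seq_len(days) - 1)
  steps_by_day <- data.frame(date = dates, steps = 0)
  for (b0 in bout_starts_s) {
    if (in_nonwear(b0)) next
    d <- floor(b0 / 86400) + 1
    if (d >= 1 && d <= days) {
      steps_by_day$steps[d] <- steps_by_day$steps[d] + steps_per_bout
    }
  }

  # noise-free per-epoch counts from the rectified-integral definition:
  # a sinusoid of amplitude A contributes A * 2/pi per second per axis.
  n_epochs <- floor(days * 86400 / 60)
  epoch_vmu <- data.frame(
    epoch_start = stream$start_time + (seq_len(n_epochs) - 1) * 60,
    vmu = 0
  )
  es <- (seq_len(n_epochs) - 1) * 60
  for (b0 in bout_starts_s) {
    if (in_nonwear(b0)) next
    overlap <- pmax(0, pmin(es + 60, b0 + bout_dur) - pmax(es, b0))
    amps <- bout_amplitude * c(0.4, 0.3, 1)     # ax, ay, az
    axis_counts <- outer(overlap, amps * (2 / pi) / 0.1)
    epoch_vmu$vmu <- epoch_vmu$vmu + sqrt(rowSums(axis_counts^2))
  }

  stream$truth <- list(steps_by_day = steps_by_day, epoch_vmu = epoch_vmu,
                       nonwear_blocks = nonwear_blocks,
                       bout_starts_s = bout_starts_s,
                       steps_per_bout = steps_per_bout)
  stream
}
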