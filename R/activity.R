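#' Detect worn/nonworn epochs from signal stillness
#'
#' An epoch is flagged nonworn when it falls inside a run of at least
#' `run_min` consecutive minutes in which the standard deviation of the
#' acceleration vector magnitude stays below `stillness_sd` — i.e. a
#' gravity-only signal. Shorter still periods (quiet sitting) remain worn.
#'
#' @param stream An `accel_stream`.
#' @param stillness_sd Stillness threshold on the per-epoch vector-magnitude
#'   SD (g); default 0.004.
#' @param run_min Minimum still run length to call nonwear (minutes);
#'   default 60.
#' @return Logical vector, one flag per complete 60-s epoch (TRUE = worn).
#' @export
detect_wear <- function(stream, stillness_sd = 0.004, run_min = 60) {
  stopifnot(inherits(stream, "accel_stream"))
  spe <- as.integer(round(60 * stream$sample_rate))
  n_epochs <- stream$n %/% spe
  if (n_epochs == 0) return(logical(0))
  vm <- sqrt(stream$ax^2 + stream$ay^2 + stream$az^2)
  vm <- vm[seq_len(n_epochs * spe)]
  m <- matrix(vm, nrow = spe)
  sds <- apply(m, 2, stats::sd)
  still <- sds < stillness_sd

  worn <- rep(TRUE, n_epochs)
  r <- rle(still)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  for (i in seq_along(r$values)) {
    if (r$values[i] && r$lengths[i] >= run_min) {
      worn[starts[i]:ends[i]] <- FALSE
    }
  }
  worn
}

# Band-pass filter one axis; interpolate NA gaps up to max_gap seconds,
# returning NA runs longer than that unchanged (their epochs get dropped).
# The upper band edge is capped below Nyquist for low-rate streams.
bandpass_axis <- function(x, fs, band, max_gap = 5, order = 3) {
  band <- c(band[1], min(band[2], 0.45 * fs))
  if (band[2] <= band[1]) {
    stop("sample rate too low for the requested pass band")
  }
  # demean first: the filter removes DC anyway, but doing it up front
  # kills the start/end transients a DC step would otherwise inject
  # (a constant gravity axis then filters to exactly zero)
  x <- x - mean(x, na.rm = TRUE)
  if (anyNA(x)) {
    r <- rle(is.na(x))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    long_na <- rep(FALSE, length(x))
    for (i in seq_along(r$values)) {
      if (r$values[i] && r$lengths[i] > max_gap * fs) {
        long_na[starts[i]:ends[i]] <- TRUE
      }
    }
    idx <- which(!is.na(x))
    if (length(idx) >= 2) {
      x <- stats::approx(idx, x[idx], xout = seq_along(x), rule = 2)$y
    } else {
      x[is.na(x)] <- 0
    }
    filt <- signal::filtfilt(signal::butter(order, band / (fs / 2), "pass"),
                             x)
    filt[long_na] <- NA_real_
    return(filt)
  }
  signal::filtfilt(signal::butter(order, band / (fs / 2), "pass"), x)
}

#' Vector-magnitude activity counts per 1-min epoch
#'
#' Each axis is band-pass filtered (removing the gravity component and
#' high-frequency content; zero-phase Butterworth whose passband is flat
#' across the locomotor band), rectified and integrated over the epoch, and
#' scaled so 1 count = `count_scale` g s. The epoch VMU is the Euclidean
#' norm of the three per-axis counts. Gaps (NA) longer than `max_gap`
#' seconds cause the affected epoch to be dropped (VMU = NA); shorter gaps
#' are linearly interpolated.
#'
#' @param stream An `accel_stream` in calibrated g units.
#' @param band Pass band (Hz); default `c(0.25, 5)`.
#' @param count_scale g-seconds per count; default 0.1.
#' @param max_gap Longest interpolatable gap (s); default 5.
#' @param ... Passed to [detect_wear()].
#' @return A data.frame of class `epoch_records` with columns `epoch_start`
#'   (POSIXct), `vmu` (counts per min) and `worn`.
#' @export
vmu_per_epoch <- function(stream, band = c(0.25, 5), count_scale = 0.1,
                          max_gap = 5, ...) {
  stopifnot(inherits(stream, "accel_stream"))
  fs <- stream$sample_rate
  spe <- as.integer(round(60 * fs))
  n_epochs <- stream$n %/% spe
  if (n_epochs == 0) {
    return(structure(data.frame(epoch_start = stream$start_time[0],
                                vmu = numeric(0), worn = logical(0)),
                     class = c("epoch_records", "data.frame")))
  }
  keep <- seq_len(n_epochs * spe)
  axis_counts <- vapply(list(stream$ax, stream$ay, stream$az), function(x) {
    f <- bandpass_axis(x[keep], fs, band, max_gap)
    colSums(matrix(abs(f), nrow = spe)) / fs / count_scale
  }, numeric(n_epochs))
  vmu <- sqrt(rowSums(axis_counts^2))

  worn <- detect_wear(stream, ...)
  structure(
    data.frame(
      epoch_start = stream$start_time + (seq_len(n_epochs) - 1) * 60,
      vmu = vmu,
      worn = worn[seq_len(n_epochs)]
    ),
    class = c("epoch_records", "data.frame")
  )
}

# Greedy peak picker with a refractory period.
find_peaks <- function(x, thr, min_gap) {
  n <- length(x)
  if (n < 3) return(integer(0))
  cand <- which(x[2:(n - 1)] > x[1:(n - 2)] &
                  x[2:(n - 1)] >= x[3:n] &
                  x[2:(n - 1)] > thr) + 1L
  if (!length(cand)) return(integer(0))
  keep <- cand[1]
  last <- cand[1]
  for (i in cand[-1]) {
    if (i - last >= min_gap) {
      keep <- c(keep, i)
      last <- i
    }
  }
  keep
}

#' Count steps from the band-limited vector magnitude
#'
#' Documented stand-in for the device's proprietary step algorithm: the
#' acceleration vector magnitude is band-pass filtered to the locomotor band
#' (default 0.5-3 Hz) and peaks above an adaptive threshold, separated by a
#' refractory period of at least `refractory` seconds, are counted as steps.
#'
#' @param stream An `accel_stream`.
#' @param band Locomotor pass band (Hz); default `c(0.5, 3)`.
#' @param refractory Minimum inter-step interval (s); default 0.25.
#' @param min_height Floor on the peak threshold (g); default 0.05.
#' @return Numeric vector of peak times (seconds since stream start), with
#'   attribute `threshold`.
#' @export
step_events <- function(stream, band = c(0.5, 3), refractory = 0.25,
                        min_height = 0.05) {
  stopifnot(inherits(stream, "accel_stream"))
  fs <- stream$sample_rate
  vm <- sqrt(stream$ax^2 + stream$ay^2 + stream$az^2)
  f <- bandpass_axis(vm, fs, band)
  f[is.na(f)] <- 0
  thr <- max(min_height,
             0.3 * stats::quantile(abs(f), 0.999, names = FALSE))
  pk <- find_peaks(f, thr, max(1L, as.integer(round(refractory * fs))))
  structure((pk - 1) / fs, threshold = thr)
}

#' Steps per day over worn daytime epochs
#'
#' Counts step events (see [step_events()]) falling in worn epochs within
#' the daytime window, aggregated per calendar day.
#'
#' @param stream An `accel_stream`.
#' @param worn Optional per-epoch worn flags (from [detect_wear()]);
#'   computed if omitted.
#' @param daytime Daytime window in hours, inclusive start, exclusive end;
#'   default `c(8, 23)`.
#' @param ... Passed to [step_events()].
#' @return A data.frame with `date` and `steps`.
#' @export
count_steps <- function(stream, worn = NULL, daytime = c(8, 23), ...) {
  stopifnot(inherits(stream, "accel_stream"))
  if (is.null(worn)) worn <- detect_wear(stream)
  ev <- step_events(stream, ...)
  n_days <- max(1L, ceiling(stream$n / stream$sample_rate / 86400))
  dates <- as.Date(stream$start_time) + seq_len(n_days) - 1
  out <- data.frame(date = dates, steps = 0L)
  if (length(ev)) {
    epoch <- floor(ev / 60) + 1
    hod <- (as.numeric(stream$start_time) %% 86400 + ev) %% 86400 / 3600
    ok <- epoch <= length(worn) & worn[pmin(epoch, length(worn))] &
      hod >= daytime[1] & hod < daytime[2]
    day <- floor(ev[ok] / 86400) + 1
    tab <- table(factor(day, levels = seq_len(n_days)))
    out$steps <- as.integer(tab)
  }
  out
}

#' Construct per-day activity records
#'
#' Either built directly (for summaries of externally processed days) or via
#' [activity_days()] from a raw stream. A day is valid when the monitor was
#' worn for at least 8 daytime hours.
#'
#' @param date Date vector.
#' @param daytime_wear_h Hours worn within the daytime window.
#' @param steps Step count.
#' @param mean_vmu Mean VMU (counts per min) over worn daytime epochs.
#' @param min_wear_h Validity threshold (h); default 8, inclusive.
#' @return A data.frame of class `day_records` with a `valid` flag.
#' @export
day_records <- function(date, daytime_wear_h, steps, mean_vmu,
                        min_wear_h = 8) {
  structure(
    data.frame(date = date, daytime_wear_h = daytime_wear_h,
               steps = steps, mean_vmu = mean_vmu,
               valid = daytime_wear_h >= min_wear_h),
    class = c("day_records", "data.frame")
  )
}

#' Summarise a stream into per-day activity records
#'
#' @param stream An `accel_stream`.
#' @param daytime Daytime window (hours); default 08:00 inclusive to 23:00
#'   exclusive.
#' @param vmu_denominator `"worn"` (default) averages VMU over worn daytime
#'   epochs only; `"all"` over all daytime epochs.
#' @param ... Passed to [vmu_per_epoch()].
#' @return A `day_records` data.frame.
#' @export
activity_days <- function(stream, daytime = c(8, 23),
                          vmu_denominator = c("worn", "all"), ...) {
  vmu_denominator <- match.arg(vmu_denominator)
  ep <- vmu_per_epoch(stream, ...)
  steps <- count_steps(stream, worn = ep$worn, daytime = daytime)

  hod <- (as.numeric(ep$epoch_start) %% 86400) / 3600
  day <- as.Date(ep$epoch_start)
  daytime_idx <- hod >= daytime[1] & hod < daytime[2]

  dates <- steps$date
  wear_h <- mvmu <- numeric(length(dates))
  for (i in seq_along(dates)) {
    sel <- day == dates[i] & daytime_idx
    worn_sel <- sel & ep$worn & !is.na(ep$vmu)
    wear_h[i] <- sum(sel & ep$worn) / 60
    denom <- if (vmu_denominator == "worn") worn_sel else
      sel & !is.na(ep$vmu)
    mvmu[i] <- if (any(denom)) mean(ep$vmu[denom]) else NA_real_
  }
  day_records(dates, wear_h, steps$steps, mvmu)
}

#' Participant-level activity summary under the validity rules
#'
#' A day is valid when worn at least 8 daytime hours; a participant is
#' compliant when at least 4 days are valid. Steps/day and VMU/min are means
#' over valid days only; with zero valid days the means are NA (explicitly
#' undefined, not zero).
#'
#' @param days A `day_records` data.frame (or any data.frame with
#'   `daytime_wear_h`, `steps`, `mean_vmu`).
#' @param min_wear_h Day validity threshold (h, inclusive); default 8.
#' @param min_days Compliance threshold (valid days, inclusive); default 4.
#' @return A list of class `activity_summary`: `n_valid_days`,
#'   `steps_per_day`, `vmu_per_min`, `compliant`.
#' @export
summarize_activity <- function(days, min_wear_h = 8, min_days = 4) {
  stopifnot(is.data.frame(days), nrow(days) >= 1,
            all(c("daytime_wear_h", "steps", "mean_vmu") %in% names(days)))
  valid <- days$daytime_wear_h >= min_wear_h
  n_valid <- sum(valid)
  structure(
    list(
      n_valid_days = n_valid,
      steps_per_day = if (n_valid) mean(days$steps[valid]) else NA_real_,
      vmu_per_min = if (n_valid) mean(days$mean_vmu[valid], na.rm = TRUE)
        else NA_real_,
      compliant = n_valid >= min_days
    ),
    class = "activity_summary"
  )
}

#' @export
print.activity_summary <- function(x, ...) {
  cat(sprintf(
    "<activity_summary> %d valid days (%scompliant): %.0f steps/day, %.0f VMU/min\n",
    x$n_valid_days, if (x$compliant) "" else "non-",
    x$steps_per_day, x$vmu_per_min))
  invisible(x)
}
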