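#' Write a NIRS recording to tidy CSV (trace + events)
#'
#' The trace file has columns `time_s, tsi_pct, thb_au, hhb_au, hbo2_au`;
#' the events file has `start_s, duration_s, kind, assessment` with kinds
#' `calibration`, `intermittent` and `contraction`.
#'
#' @param rec A `nirs_recording`.
#' @param trace_path,events_path Output file paths.
#' @return Invisibly, the two paths.
#' @export
write_nirs_csv <- function(rec, trace_path, events_path) {
  stopifnot(inherits(rec, "nirs_recording"))
  trace <- data.frame(time_s = rec$time, tsi_pct = rec$tsi,
                      thb_au = rec$thb, hhb_au = rec$hhb,
                      hbo2_au = rec$hbo2)
  utils::write.csv(trace, trace_path, row.names = FALSE)
  ev <- rec$schedule$events
  con <- rec$schedule$contractions
  events <- rbind(
    data.frame(start_s = ev$start_s, duration_s = ev$duration_s,
               kind = ev$kind, assessment = ev$assessment),
    data.frame(start_s = con$start_s, duration_s = con$duration_s,
               kind = "contraction", assessment = con$assessment)
  )
  events <- events[order(events$start_s), ]
  utils::write.csv(events, events_path, row.names = FALSE)
  invisible(c(trace_path, events_path))
}

#' Read a NIRS recording from tidy CSV (trace + events)
#'
#' @param trace_path,events_path Paths written by [write_nirs_csv()] (or
#'   any files in the same dialect).
#' @return A `nirs_recording` (without simulation ground truth).
#' @export
read_nirs_recording <- function(trace_path, events_path) {
  trace <- utils::read.csv(trace_path)
  need <- c("time_s", "tsi_pct", "thb_au", "hhb_au", "hbo2_au")
  stopifnot(all(need %in% names(trace)))
  if (any(diff(trace$time_s) <= 0)) stop("time must be strictly increasing")
  if (any(trace$tsi_pct < 0 | trace$tsi_pct > 100, na.rm = TRUE)) {
    stop("TSI must lie within [0, 100]")
  }
  events <- utils::read.csv(events_path)
  stopifnot(all(c("start_s", "duration_s", "kind") %in% names(events)))
  if (!"assessment" %in% names(events)) events$assessment <- NA_integer_
  occ <- events[events$kind %in% c("calibration", "intermittent"), ]
  con <- events[events$kind == "contraction", ]
  sched <- structure(
    list(events = occ[c("start_s", "duration_s", "kind", "assessment")],
         contractions = con[c("start_s", "duration_s", "assessment")],
         total_duration = max(trace$time_s), seed = NA_integer_),
    class = "occlusion_schedule"
  )
  validate_schedule(sched)
  fs <- 1 / stats::median(diff(trace$time_s))
  structure(
    list(time = trace$time_s, tsi = trace$tsi_pct, thb = trace$thb_au,
         hhb = trace$hhb_au, hbo2 = trace$hbo2_au, schedule = sched,
         sample_rate = fs, truth = NULL),
    class = "nirs_recording"
  )
}

#' Write an accelerometer stream to CSV
#'
#' Columns: `timestamp_iso, ax_g, ay_g, az_g`. Intended for short streams;
#' multi-day 100 Hz streams are better kept in memory.
#'
#' @param stream An `accel_stream`.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_accel_csv <- function(stream, path) {
  stopifnot(inherits(stream, "accel_stream"))
  ts <- stream$start_time + stream_seconds(stream)
  df <- data.frame(
    timestamp_iso = format(ts, "%Y-%m-%dT%H:%M:%OS3", tz = "UTC"),
    ax_g = stream$ax, ay_g = stream$ay, az_g = stream$az)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read an accelerometer stream from CSV
#'
#' @param path CSV with `timestamp_iso, ax_g, ay_g, az_g`; the sample rate
#'   is inferred from the median timestamp spacing and must be within 1%%
#'   of constant.
#' @return An `accel_stream`.
#' @export
read_accel_stream <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("timestamp_iso", "ax_g", "ay_g", "az_g") %in% names(df)))
  ts <- as.POSIXct(df$timestamp_iso, format = "%Y-%m-%dT%H:%M:%OS",
                   tz = "UTC")
  dt <- diff(as.numeric(ts))
  med <- stats::median(dt)
  if (any(abs(dt - med) > 0.01 * med + 1e-4)) {
    stop("sample spacing varies by more than 1% of nominal")
  }
  accel_stream(df$ax_g, df$ay_g, df$az_g, sample_rate = 1 / med,
               start_time = ts[1])
}

#' Write / read a cohort table as CSV
#'
#' @param cohort A `cohort_table` data.frame.
#' @param path CSV path.
#' @return `write_cohort_csv` the path (invisibly); `read_cohort_csv` a
#'   `cohort_table`.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  dat <- utils::read.csv(path)
  if ("group" %in% names(dat)) {
    dat$group <- factor(dat$group, levels = group_levels())
  }
  class(dat) <- c("cohort_table", "data.frame")
  dat
}
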