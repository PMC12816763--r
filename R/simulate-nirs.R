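#' Simulation parameters for a NIRS oxidative-capacity recording
#'
#' Bundles the ground-truth physiology used by [simulate_nirs_recording()].
#' Muscle oxygen consumption (mVO2) is expressed on the tissue-saturation
#' scale, i.e. as the magnitude of TSI decline per second during arterial
#' occlusion, so the proportionality constant between the occlusion slope and
#' mVO2 is 1.
#'
#' @param k_true True recovery rate constant of mVO2 (min^-1, > 0).
#' @param mvo2_rest Resting oxygen consumption (TSI %% per s, >= 0).
#' @param mvo2_peak Consumption immediately after the contraction bout
#'   (TSI %% per s, > `mvo2_rest`).
#' @param tsi_baseline Resting tissue saturation index (%%, 0-100).
#' @param tsi_min Ischemic TSI plateau reached during the calibration
#'   occlusion (%%, < `tsi_baseline`).
#' @param tsi_peak Hyperaemic overshoot maximum reached on cuff release
#'   (%%, > `tsi_baseline`). Together with `tsi_min` this defines the
#'   individualized physiological saturation range.
#' @param reperfusion_rate First-order resaturation rate toward baseline
#'   between occlusions (s^-1, > 0).
#' @param noise_sd Additive Gaussian noise on TSI (%% units, >= 0). The
#'   default 0.10 is calibrated so that duplicate assessments of the
#'   default protocol reproduce the test-retest reliability reported for
#'   this measurement class (ICC of about 0.88).
#' @param sample_rate Sampling frequency (Hz, > 0). Default 10 Hz
#'   (continuous-wave spatially resolved device class).
#' @param desat_target Fraction of the physiological range to which the
#'   pre-assessment contractions desaturate the muscle (default 0.5).
#' @param seed Integer seed controlling the noise draw.
#'
#' @return An object of class `nirs_sim_params`.
#' @export
nirs_sim_params <- function(k_true = 1.67,
                            mvo2_rest = 0.02,
                            mvo2_peak = 0.35,
                            tsi_baseline = 70,
                            tsi_min = 35,
                            tsi_peak = 78,
                            reperfusion_rate = 0.15,
                            noise_sd = 0.10,
                            sample_rate = 10,
                            desat_target = 0.5,
                            seed = 1L) {
  stopifnot(
    is.numeric(k_true), length(k_true) == 1L, k_true > 0,
    mvo2_rest >= 0, mvo2_peak > mvo2_rest,
    tsi_baseline > 0, tsi_baseline <= 100,
    tsi_min < tsi_baseline, tsi_min >= 0,
    tsi_peak > tsi_baseline, tsi_peak <= 100,
    reperfusion_rate > 0, noise_sd >= 0, sample_rate > 0,
    desat_target > 0, desat_target < 1
  )
  structure(
    list(
      k_true = k_true, mvo2_rest = mvo2_rest, mvo2_peak = mvo2_peak,
      tsi_baseline = tsi_baseline, tsi_min = tsi_min, tsi_peak = tsi_peak,
      reperfusion_rate = reperfusion_rate, noise_sd = noise_sd,
      sample_rate = sample_rate, desat_target = desat_target,
      seed = as.integer(seed)
    ),
    class = "nirs_sim_params"
  )
}

#' Occlusion/contraction schedule for the oxidative-capacity protocol
#'
#' Builds the event timeline of the assessment protocol: a resting baseline,
#' a calibration arterial occlusion (held until a stable TSI minimum, capped
#' at 5 min) followed by reactive reoxygenation, then `n_assessments`
#' duplicate assessments, each consisting of a brief contraction bout and a
#' series of intermittent arterial occlusions (by default 5 occlusions of
#' 5 s then 10 of 10 s, separated by recovery gaps drawn uniformly from
#' `gap_range`).
#'
#' @param n_assessments Number of duplicate assessments (default 2).
#' @param n_short,short_dur Count and duration (s) of the short occlusions.
#' @param n_long,long_dur Count and duration (s) of the long occlusions.
#' @param gap_range Range (s) of the uniform recovery gaps between
#'   occlusions; default `c(5, 20)`.
#' @param contraction_dur Duration (s) of each contraction bout.
#' @param baseline_dur Initial resting baseline (s).
#' @param calibration_dur Duration (s) of the calibration occlusion
#'   (<= 300 s).
#' @param reperfusion_dur Reoxygenation window after the calibration
#'   occlusion (s).
#' @param rest_between Rest (s) between duplicate assessments.
#' @param tail_dur Trailing recording time after the final occlusion (s).
#' @param seed Integer seed fixing the gap draws.
#'
#' @return An object of class `occlusion_schedule` with components
#'   `events` (data.frame: start_s, duration_s, kind, assessment) and
#'   `contractions` (data.frame: start_s, duration_s, assessment; the
#'   calibration-priming bout has assessment 0).
#' @export
occlusion_schedule <- function(n_assessments = 2,
                               n_short = 5, short_dur = 5,
                               n_long = 10, long_dur = 10,
                               gap_range = c(5, 20),
                               contraction_dur = 12,
                               baseline_dur = 120,
                               calibration_dur = 240,
                               reperfusion_dur = 180,
                               rest_between = 120,
                               tail_dur = 60,
                               seed = 1L) {
  stopifnot(n_assessments >= 1, calibration_dur <= 300,
            length(gap_range) == 2L, gap_range[1] >= 0,
            gap_range[2] >= gap_range[1])
  n_occ <- n_short + n_long
  durs <- c(rep(short_dur, n_short), rep(long_dur, n_long))
  gaps <- withr_seed(seed, function() {
    matrix(stats::runif(n_occ * n_assessments, gap_range[1], gap_range[2]),
           nrow = n_occ)
  })

  t <- baseline_dur
  contractions <- data.frame(start_s = t, duration_s = contraction_dur,
                             assessment = 0L)
  t <- t + contraction_dur
  events <- data.frame(start_s = t, duration_s = calibration_dur,
                       kind = "calibration", assessment = 0L)
  t <- t + calibration_dur + reperfusion_dur

  for (a in seq_len(n_assessments)) {
    contractions <- rbind(contractions,
                          data.frame(start_s = t, duration_s = contraction_dur,
                                     assessment = a))
    t <- t + contraction_dur
    for (i in seq_len(n_occ)) {
      events <- rbind(events,
                      data.frame(start_s = t, duration_s = durs[i],
                                 kind = "intermittent", assessment = a))
      t <- t + durs[i] + gaps[i, a]
    }
    if (a < n_assessments) t <- t + rest_between
  }
  total <- t + tail_dur

  sched <- structure(
    list(events = events, contractions = contractions,
         total_duration = total, seed = as.integer(seed)),
    class = "occlusion_schedule"
  )
  validate_schedule(sched)
  sched
}

validate_schedule <- function(sched) {
  ev <- rbind(
    sched$events[c("start_s", "duration_s")],
    sched$contractions[c("start_s", "duration_s")]
  )
  ev <- ev[order(ev$start_s), ]
  if (any(diff(ev$start_s) <= 0)) {
    stop("schedule events must be strictly increasing")
  }
  ends <- ev$start_s + ev$duration_s
  if (any(ends[-nrow(ev)] > ev$start_s[-1] + 1e-9)) {
    stop("schedule events overlap")
  }
  invisible(sched)
}

# Run fn under a local RNG seed without disturbing the caller's RNG state.
withr_seed <- function(seed, fn) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  fn()
}

#' Simulate an annotated NIRS recording with known kinetics
#'
#' Generates a TSI trace (plus THb/HHb/HbO2 channels) following the
#' oxidative-capacity protocol in `schedule`. After the final contraction of
#' each assessment (time t0), muscle oxygen consumption follows
#' `mvo2(t) = mvo2_rest + (mvo2_peak - mvo2_rest) * exp(-k_true/60 * (t - t0))`.
#' Within each arterial occlusion oxygen delivery is zero, so
#' `dTSI/dt = -mvo2(t)` (integrated in closed form); between occlusions TSI
#' relaxes first-order toward `tsi_baseline` at `reperfusion_rate`. Gaussian
#' noise of sd `noise_sd` is added per sample.
#'
#' @param params A [nirs_sim_params()] object.
#' @param schedule An [occlusion_schedule()] object.
#' @param duration Optional total duration (s); must be at least the
#'   schedule's span. Defaults to the schedule's span.
#'
#' @return An object of class `nirs_recording`: components `time`, `tsi`,
#'   `thb`, `hhb`, `hbo2`, `schedule`, `sample_rate`, and a `truth` list with
#'   the generating parameters and per-assessment t0.
#' @export
simulate_nirs_recording <- function(params, schedule, duration = NULL) {
  stopifnot(inherits(params, "nirs_sim_params"),
            inherits(schedule, "occlusion_schedule"))
  if (is.null(duration)) duration <- schedule$total_duration
  if (schedule$total_duration > duration + 1e-9) {
    stop("schedule extends past trace duration")
  }

  fs <- params$sample_rate
  time <- seq(0, duration, by = 1 / fs)
  k_s <- params$k_true / 60
  dmv <- params$mvo2_peak - params$mvo2_rest
  desat_tsi <- params$tsi_peak -
    params$desat_target * (params$tsi_peak - params$tsi_min)

  # Build an ordered piecewise segment list; each segment knows how to
  # evaluate TSI analytically given the value at its start.
  segs <- build_segments(params, schedule, duration, desat_tsi)

  tsi <- numeric(length(time))
  t0_by_assessment <- attr(segs, "t0")
  s0 <- params$tsi_baseline
  for (seg in segs) {
    idx <- which(time >= seg$t_start - 1e-9 & time < seg$t_end - 1e-9)
    f <- segment_fun(seg, params, k_s, dmv, t0_by_assessment)
    if (length(idx)) tsi[idx] <- f(time[idx], s0)
    s0 <- f(seg$t_end, s0)
  }
  tsi[length(time)] <- s0

  if (any(tsi < 0)) {
    stop("simulated TSI crosses below 0; parameters implausible")
  }

  thb0 <- 100
  noise <- withr_seed(params$seed, function() {
    list(tsi = stats::rnorm(length(time), 0, params$noise_sd),
         thb = stats::rnorm(length(time), 0, params$noise_sd * 0.2))
  })
  tsi_noisy <- pmin(100, pmax(0, tsi + noise$tsi))
  thb <- thb0 + noise$thb
  hhb <- thb * (1 - tsi_noisy / 100)
  hbo2 <- thb - hhb

  structure(
    list(time = time, tsi = tsi_noisy, thb = thb, hhb = hhb, hbo2 = hbo2,
         schedule = schedule, sample_rate = fs,
         truth = list(params = params, t0 = t0_by_assessment,
                      tsi_clean = tsi)),
    class = "nirs_recording"
  )
}

build_segments <- function(params, schedule, duration, desat_tsi) {
  ev <- schedule$events
  con <- schedule$contractions
  marks <- rbind(
    data.frame(start = ev$start_s, end = ev$start_s + ev$duration_s,
               type = ifelse(ev$kind == "calibration",
                             "cal_occlusion", "occlusion"),
               assessment = ev$assessment),
    data.frame(start = con$start_s, end = con$start_s + con$duration_s,
               type = "contraction", assessment = con$assessment)
  )
  marks <- marks[order(marks$start), ]

  t0 <- numeric(0)
  segs <- list()
  cursor <- 0
  for (i in seq_len(nrow(marks))) {
    m <- marks[i, ]
    if (m$start > cursor + 1e-9) {
      # Gap segment: reoxygenation toward target.
      if (length(segs) && segs[[length(segs)]]$type == "cal_occlusion") {
        # hyperaemic overshoot, then relaxation to baseline
        t_ov <- min(cursor + 40, m$start)
        segs <- c(segs, list(list(t_start = cursor, t_end = t_ov,
                                  type = "resat")))
        if (m$start > t_ov + 1e-9) {
          segs <- c(segs, list(list(t_start = t_ov, t_end = m$start,
                                    type = "relax")))
        }
      } else {
        segs <- c(segs, list(list(t_start = cursor, t_end = m$start,
                                  type = "relax")))
      }
    }
    seg <- list(t_start = m$start, t_end = m$end, type = m$type,
                assessment = m$assessment)
    if (m$type == "contraction") {
      seg$target <- if (m$assessment == 0L) params$tsi_baseline - 5 else
        desat_tsi
      if (m$assessment > 0L) t0[m$assessment] <- m$end
    }
    segs <- c(segs, list(seg))
    cursor <- m$end
  }
  if (duration > cursor + 1e-9) {
    segs <- c(segs, list(list(t_start = cursor, t_end = duration,
                              type = "relax")))
  }
  attr(segs, "t0") <- t0
  segs
}

segment_fun <- function(seg, params, k_s, dmv, t0) {
  ts <- seg$t_start
  switch(seg$type,
    relax = function(t, s0) {
      params$tsi_baseline +
        (s0 - params$tsi_baseline) * exp(-params$reperfusion_rate * (t - ts))
    },
    resat = function(t, s0) {
      params$tsi_peak - (params$tsi_peak - s0) * exp(-0.2 * (t - ts))
    },
    contraction = function(t, s0) {
      s0 + (seg$target - s0) * (t - ts) / (seg$t_end - ts)
    },
    cal_occlusion = function(t, s0) {
      params$tsi_min + (s0 - params$tsi_min) * exp(-0.03 * (t - ts))
    },
    occlusion = function(t, s0) {
      t0a <- t0[seg$assessment]
      # closed-form integral of mvo2 over [ts, t]
      consumed <- params$mvo2_rest * (t - ts) +
        (dmv / k_s) * (exp(-k_s * (ts - t0a)) - exp(-k_s * (t - t0a)))
      s0 - consumed
    },
    stop("unknown segment type: ", seg$type)
  )
}

#' @export
print.nirs_recording <- function(x, ...) {
  n_occ <- sum(x$schedule$events$kind == "intermittent")
  cat("<nirs_recording> ", length(x$time), " samples @ ", x$sample_rate,
      " Hz (", round(max(x$time) / 60, 1), " min), ",
      n_occ, " intermittent occlusions, ",
      max(x$schedule$events$assessment), " assessments\n", sep = "")
  invisible(x)
}

#' @export
print.occlusion_schedule <- function(x, ...) {
  cat("<occlusion_schedule> ", nrow(x$events), " occlusion events, ",
      nrow(x$contractions), " contraction bouts, span ",
      round(x$total_duration, 1), " s\n", sep = "")
  invisible(x)
}

#' True mVO2 value of a simulated recording at given recovery times
#'
#' Analytic oracle: the generating exponential evaluated at `t` seconds after
#' the end of an assessment's final contraction.
#'
#' @param rec A simulated `nirs_recording`.
#' @param t Seconds since the end of the contraction bout.
#' @return mVO2 in TSI %% per s.
#' @export
true_mvo2 <- function(rec, t) {
  p <- rec$truth$params
  p$mvo2_rest + (p$mvo2_peak - p$mvo2_rest) * exp(-(p$k_true / 60) * t)
}
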