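#' Arterial-occlusion quality check
#'
#' Verifies the spectroscopic signature of a true arterial occlusion over a
#' check window of at least 15 s: deoxygenated haemoglobin+myoglobin (HHb)
#' rising, oxygenated haemoglobin+myoglobin (HbO2) falling, and total
#' haemoglobin (THb) stable. Slopes are assessed by simple linear regression;
#' "rising"/"falling" require the one-sided slope test to exclude zero at
#' `alpha`, and THb stability requires the total drift over the window to be
#' below `thb_tol` of the onset THb.
#'
#' @param rec A `nirs_recording` (simulated or read from file).
#' @param window Numeric `c(start_s, duration_s)` of the check window, or a
#'   single row of `rec$schedule$events`.
#' @param thb_tol Allowed relative THb drift over the window (default 0.05).
#' @param alpha One-sided significance level for the channel slopes.
#'
#' @return A list with `status` ("pass", "fail" or "indeterminate") and a
#'   `details` list of the per-channel slope statistics.
#' @export
check_arterial_occlusion <- function(rec, window, thb_tol = 0.05,
                                     alpha = 0.05) {
  stopifnot(inherits(rec, "nirs_recording"))
  if (is.data.frame(window)) {
    window <- c(window$start_s[1], window$duration_s[1])
  }
  if (window[2] < 15) stop("check window must be at least 15 s")
  idx <- rec$time >= window[1] & rec$time <= window[1] + window[2]
  if (sum(idx) < 4) stop("check window contains too few samples")
  tt <- rec$time[idx]

  chans <- list(hhb = rec$hhb[idx], hbo2 = rec$hbo2[idx],
                thb = rec$thb[idx])
  if (any(vapply(chans, function(x) all(is.na(x)), logical(1)))) {
    return(list(status = "indeterminate",
                details = list(reason = "missing channel")))
  }

  slope_stat <- function(y) {
    fit <- stats::lm(y ~ tt)
    s <- summary(fit)$coefficients
    if (nrow(s) < 2 || is.na(s[2, 2]) || s[2, 2] == 0) {
      return(c(slope = unname(stats::coef(fit)[2]), t = NA_real_))
    }
    c(slope = s[2, 1], t = s[2, 1] / s[2, 2])
  }
  hhb <- slope_stat(chans$hhb)
  hbo2 <- slope_stat(chans$hbo2)
  thb_fit <- stats::lm(chans$thb ~ tt)
  thb_drift <- abs(stats::coef(thb_fit)[2] * window[2])
  thb_onset <- abs(chans$thb[1])
  if (thb_onset == 0) thb_onset <- mean(abs(chans$thb))

  df <- length(tt) - 2
  tcrit <- stats::qt(1 - alpha, df)
  hhb_up <- is.finite(hhb["t"]) && hhb["t"] > tcrit
  hbo2_down <- is.finite(hbo2["t"]) && hbo2["t"] < -tcrit
  thb_stable <- thb_drift < thb_tol * thb_onset

  list(
    status = if (hhb_up && hbo2_down && thb_stable) "pass" else "fail",
    details = list(hhb_slope = unname(hhb["slope"]), hhb_t = unname(hhb["t"]),
                   hbo2_slope = unname(hbo2["slope"]),
                   hbo2_t = unname(hbo2["t"]),
                   thb_drift = unname(thb_drift),
                   thb_drift_frac = unname(thb_drift / thb_onset))
  )
}

# Rolling OLS slope of y over windows of n samples spaced dt apart.
# Returns a vector aligned to the window's *last* sample (leading NAs).
rolling_slope <- function(y, n, dt) {
  if (n < 2 || length(y) < n) return(rep(NA_real_, length(y)))
  w <- seq_len(n) - (n + 1) / 2
  num <- stats::filter(y, rev(w), sides = 1)
  as.numeric(num) / (sum(w^2) * dt)
}

rolling_mean <- function(y, n) {
  if (n < 1 || length(y) < n) return(y)
  as.numeric(stats::filter(y, rep(1 / n, n), sides = 1))
}

#' Individualized physiological saturation range
#'
#' Locates the calibration arterial occlusion in the recording, finds the
#' stable TSI minimum as the mean of the terminal plateau (rolling
#' `plateau_window`-second slope within `plateau_tol` of zero), and the TSI
#' maximum as the peak of the smoothed trace during the reactive
#' reoxygenation that follows cuff release. If no plateau is reached the
#' occlusion is only accepted when it lasted the 5-min cap.
#'
#' @param rec A `nirs_recording` containing a calibration occlusion.
#' @param plateau_tol Absolute slope tolerance (TSI %% per s) defining the
#'   plateau; default 0.005.
#' @param plateau_window Plateau slope window (s); default 10.
#' @param smooth_window Smoothing window (s) for the reoxygenation peak;
#'   default 2.
#' @param reperfusion_span How long after cuff release to search for the
#'   peak (s); default 180.
#' @param max_occlusion The protocol cap on the calibration occlusion (s);
#'   default 300.
#'
#' @return A list of class `physiological_range` with `tsi_max`, `tsi_min`.
#' @export
physiological_range <- function(rec, plateau_tol = 0.005,
                                plateau_window = 10, smooth_window = 2,
                                reperfusion_span = 180,
                                max_occlusion = 300) {
  stopifnot(inherits(rec, "nirs_recording"))
  ev <- rec$schedule$events
  cal <- ev[ev$kind == "calibration", , drop = FALSE]
  if (nrow(cal) == 0) stop("recording has no calibration occlusion")
  cal <- cal[1, ]
  fs <- rec$sample_rate
  idx <- which(rec$time >= cal$start_s &
                 rec$time <= cal$start_s + cal$duration_s)
  y <- rec$tsi[idx]
  nwin <- max(3L, round(plateau_window * fs))
  # Smooth before the slope so the plateau rule reflects the underlying
  # trace, not sample noise.
  ys <- rolling_mean(y, max(1L, round(smooth_window * fs)))
  sl <- rolling_slope(ys, nwin, 1 / fs)
  flat <- !is.na(sl) & abs(sl) <= plateau_tol
  if (length(flat) && flat[length(flat)]) {
    run_start <- max(which(!flat), 0L) + 1L
    # the rolling window ending at run_start spans earlier samples too
    first <- max(1L, run_start - nwin + 1L)
    tsi_min <- mean(y[first:length(y)])
  } else if (cal$duration_s >= max_occlusion - 1e-9) {
    tail_n <- min(length(y), nwin)
    tsi_min <- mean(y[(length(y) - tail_n + 1):length(y)])
  } else {
    stop("calibration incomplete: no stable TSI minimum and occlusion < 5 min")
  }

  rel_end <- cal$start_s + cal$duration_s
  ridx <- which(rec$time > rel_end & rec$time <= rel_end + reperfusion_span)
  if (!length(ridx)) stop("no reperfusion data after calibration occlusion")
  smoothed <- rolling_mean(rec$tsi[ridx], max(1L, round(smooth_window * fs)))
  tsi_max <- max(smoothed, na.rm = TRUE)

  if (tsi_max <= tsi_min) stop("degenerate physiological range: tsi_max <= tsi_min")
  structure(list(tsi_max = tsi_max, tsi_min = tsi_min),
            class = "physiological_range")
}

#' @export
print.physiological_range <- function(x, ...) {
  cat(sprintf("<physiological_range> TSI min %.1f%%, max %.1f%% (span %.1f)\n",
              x$tsi_min, x$tsi_max, x$tsi_max - x$tsi_min))
  invisible(x)
}

#' Desaturation depth as a fraction of the physiological range
#'
#' `(tsi_max - tsi) / (tsi_max - tsi_min)`: 0 at the hyperaemic maximum, 1 at
#' the ischemic minimum. The protocol targets ~50%; values outside
#' `flag_range` are flagged for QC.
#'
#' @param tsi TSI (%%) at the end of the contraction bout.
#' @param range A `physiological_range`.
#' @param flag_range Acceptable fraction interval (default `c(0.3, 0.7)`).
#' @return The fraction, with attribute `in_range`.
#' @export
desaturation_fraction <- function(tsi, range, flag_range = c(0.3, 0.7)) {
  stopifnot(inherits(range, "physiological_range"))
  span <- range$tsi_max - range$tsi_min
  if (!is.finite(span) || span <= 0) stop("degenerate physiological range")
  f <- (range$tsi_max - tsi) / span
  attr(f, "in_range") <- f >= flag_range[1] & f <= flag_range[2]
  f
}

#' Per-occlusion mVO2 point values
#'
#' For each intermittent arterial occlusion, fits an ordinary least-squares
#' line to TSI over the occlusion window (after trimming `trim_start` s from
#' the beginning — cuff-inflation transient — and `trim_end` s from the end)
#' and reports mVO2 as the negative of the slope, so desaturation gives a
#' positive value. Each point is timed at the window midpoint relative to
#' the end of its assessment's final contraction. Points with a
#' non-positive value (TSI not falling) are kept but flagged unusable;
#' windows with fewer than `min_samples` usable samples are dropped with a
#' logged reason.
#'
#' @param rec A `nirs_recording`.
#' @param trim_start,trim_end Seconds trimmed from each occlusion window
#'   before the slope fit (defaults 1 and 0.5).
#' @param min_samples Minimum samples required per window (default 3).
#'
#' @return A data.frame of class `mvo2_points` with columns `assessment`,
#'   `t` (s since contraction end), `value` (%% per s), `r2`, `n_samples`,
#'   `w` (design precision of the slope, the within-window sum of squared
#'   centred times: longer occlusions give proportionally more precise
#'   slopes under homogeneous TSI noise), `usable`; dropped windows are
#'   recorded in attribute `dropped`.
#' @export
occlusion_slopes <- function(rec, trim_start = 1, trim_end = 0.5,
                             min_samples = 3L) {
  stopifnot(inherits(rec, "nirs_recording"))
  ev <- rec$schedule$events
  occ <- ev[ev$kind == "intermittent", , drop = FALSE]
  if (nrow(occ) == 0) stop("recording has no intermittent occlusions")
  con <- rec$schedule$contractions
  con <- con[con$assessment > 0, , drop = FALSE]
  t0 <- stats::setNames(con$start_s + con$duration_s, con$assessment)

  out <- vector("list", nrow(occ))
  dropped <- character(0)
  for (i in seq_len(nrow(occ))) {
    w0 <- occ$start_s[i] + trim_start
    w1 <- occ$start_s[i] + occ$duration_s[i] - trim_end
    idx <- which(rec$time >= w0 & rec$time <= w1)
    if (length(idx) < min_samples) {
      dropped <- c(dropped, sprintf(
        "occlusion %d (t=%.1fs): only %d samples after trimming",
        i, occ$start_s[i], length(idx)))
      next
    }
    tt <- rec$time[idx]
    yy <- rec$tsi[idx]
    fit <- stats::lm(yy ~ tt)
    slope <- unname(stats::coef(fit)[2])
    sst <- sum((yy - mean(yy))^2)
    # direct R^2 avoids summary.lm noise on noise-free windows
    r2 <- if (sst > 0) 1 - sum(stats::resid(fit)^2) / sst else 1
    a <- as.character(occ$assessment[i])
    out[[i]] <- data.frame(
      assessment = occ$assessment[i],
      t = mean(c(w0, w1)) - t0[[a]],
      value = -slope,
      r2 = r2,
      n_samples = length(idx),
      w = sum((tt - mean(tt))^2)
    )
  }
  pts <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  pts$usable <- pts$value > 0
  class(pts) <- c("mvo2_points", "data.frame")
  attr(pts, "dropped") <- dropped
  pts
}

#' Fit the monoexponential mVO2 recovery and extract k
#'
#' Nonlinear least squares of
#' `value = asymptote + amplitude * exp(-k/60 * t)` (t in seconds, k in
#' min^-1) over the usable mVO2 points, with bounds asymptote >= 0,
#' amplitude > 0, k > 0 and multistart initial guesses for k. Points are
#' inverse-variance weighted by default: under homogeneous TSI noise the
#' variance of an occlusion slope is inversely proportional to the
#' window's sum of squared centred times (the `w` column produced by
#' [occlusion_slopes()]), so 10-s occlusions earn proportionally more
#' weight than 5-s ones. The fit is marked non-converged when every start
#' fails or the best k sits at the box bound.
#'
#' @param points An `mvo2_points` data.frame (or any data.frame with `t`,
#'   `value` and optionally `usable` and `w`).
#' @param k_init Multistart initial values for k (min^-1).
#' @param k_max Upper box bound on k (min^-1); default 30.
#' @param min_points Minimum usable points (default 5).
#' @param min_span Minimum time span of the points (s); default 60.
#' @param weights `"design"` (default) uses the `w` column when present
#'   (equal weights otherwise), `"equal"` forces unweighted least squares,
#'   or a numeric vector of per-point weights.
#'
#' @return A list of class `kinetics_fit`: `k` (min^-1), `amplitude`,
#'   `asymptote` (%% per s), `ssr` (weighted, normalised to mean weight 1),
#'   `converged`, `n_points`.
#' @export
fit_recovery <- function(points, k_init = c(0.5, 1.5, 3.0), k_max = 30,
                         min_points = 5L, min_span = 60,
                         weights = "design") {
  stopifnot(is.data.frame(points), all(c("t", "value") %in% names(points)))
  if (is.numeric(weights)) {
    stopifnot(length(weights) == nrow(points), all(weights > 0))
    points$..w <- weights
  } else if (identical(weights, "design") && "w" %in% names(points)) {
    points$..w <- points$w
  } else {
    points$..w <- 1
  }
  if ("usable" %in% names(points)) points <- points[points$usable, ]
  points <- points[is.finite(points$t) & is.finite(points$value), ]
  if (nrow(points) < min_points) {
    stop("need at least ", min_points, " usable mVO2 points")
  }
  if (diff(range(points$t)) < min_span) {
    stop("mVO2 points must span at least ", min_span, " s")
  }
  if (stats::var(points$value) == 0) stop("no recovery signal: all points equal")

  tt <- points$t
  yy <- points$value
  ww <- points$..w / mean(points$..w)
  amp0 <- max(yy) - min(yy)
  asy0 <- max(min(yy), 1e-6)

  best <- NULL
  for (k0 in k_init) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        yy ~ asymptote + amplitude * exp(-(k / 60) * tt),
        start = list(asymptote = asy0, amplitude = max(amp0, 1e-6), k = k0),
        lower = c(asymptote = 0, amplitude = 1e-9, k = 1e-9),
        upper = c(asymptote = Inf, amplitude = Inf, k = k_max),
        weights = ww,
        control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-12,
                                             ptol = 1e-12)
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    ssr <- sum(ww * stats::resid(fit)^2)
    if (is.null(best) || ssr < best$ssr - 1e-15) {
      cf <- stats::coef(fit)
      best <- list(k = unname(cf["k"]), amplitude = unname(cf["amplitude"]),
                   asymptote = unname(cf["asymptote"]), ssr = ssr)
    }
  }
  if (is.null(best)) {
    return(structure(list(k = NA_real_, amplitude = NA_real_,
                          asymptote = NA_real_, ssr = NA_real_,
                          converged = FALSE, n_points = nrow(points)),
                     class = "kinetics_fit"))
  }
  at_bound <- best$k >= k_max * (1 - 1e-6) || best$k <= 1e-6
  structure(
    c(best, list(converged = !at_bound, n_points = nrow(points))),
    class = "kinetics_fit"
  )
}

#' @export
print.kinetics_fit <- function(x, ...) {
  cat(sprintf(
    "<kinetics_fit> k = %.3f min^-1 (amplitude %.4f, asymptote %.4f %%/s), %d points, SSR %.3g%s\n",
    x$k, x$amplitude, x$asymptote, x$n_points, x$ssr,
    if (x$converged) "" else " [NOT CONVERGED]"))
  invisible(x)
}

#' Full oxidative-capacity assessment of a recording
#'
#' Runs the complete pipeline on a recording containing duplicate
#' intermittent-occlusion assessments: physiological range, arterial
#' occlusion QC (first 20 s of the calibration occlusion), desaturation
#' depth at the end of each assessment's contraction bout, per-occlusion
#' slopes and the recovery fit per assessment. `k_mean` is the arithmetic
#' mean of the converged k estimates; if no fit converges the estimate is
#' not determinable and an error is raised.
#'
#' @param rec A `nirs_recording` with at least one assessment.
#' @param ... Passed to [occlusion_slopes()] and [fit_recovery()].
#'
#' @return A list of class `oxcap_result`: `fits` (one `kinetics_fit` per
#'   assessment), `k_mean`, `qc` (arterial check, desaturation fractions,
#'   convergence flags), `slopes`, `range`.
#' @export
oxidative_capacity <- function(rec, ...) {
  stopifnot(inherits(rec, "nirs_recording"))
  dots <- list(...)
  slope_args <- dots[names(dots) %in% c("trim_start", "trim_end",
                                        "min_samples")]
  fit_args <- dots[names(dots) %in% c("k_init", "k_max", "min_points",
                                      "min_span")]

  range <- tryCatch(physiological_range(rec), error = function(e) NULL)
  cal <- rec$schedule$events[rec$schedule$events$kind == "calibration", ]
  arterial <- if (nrow(cal)) {
    check_arterial_occlusion(rec, c(cal$start_s[1],
                                    min(20, cal$duration_s[1])))
  } else list(status = "indeterminate", details = list())

  slopes <- do.call(occlusion_slopes, c(list(rec), slope_args))
  assessments <- sort(unique(slopes$assessment))

  con <- rec$schedule$contractions
  desat <- rep(NA_real_, length(assessments))
  if (!is.null(range)) {
    for (j in seq_along(assessments)) {
      a <- assessments[j]
      ce <- con$start_s[con$assessment == a] +
        con$duration_s[con$assessment == a]
      i <- which.min(abs(rec$time - ce))
      desat[j] <- as.numeric(desaturation_fraction(rec$tsi[i], range))
    }
  }

  fits <- lapply(assessments, function(a) {
    tryCatch(
      do.call(fit_recovery,
              c(list(slopes[slopes$assessment == a, ]), fit_args)),
      error = function(e) {
        structure(list(k = NA_real_, amplitude = NA_real_,
                       asymptote = NA_real_, ssr = NA_real_,
                       converged = FALSE, n_points = 0L,
                       error = conditionMessage(e)),
                  class = "kinetics_fit")
      })
  })
  ks <- vapply(fits, function(f) if (isTRUE(f$converged)) f$k else NA_real_,
               numeric(1))
  if (all(is.na(ks))) stop("k not determinable: no assessment fit converged")

  structure(
    list(
      fits = fits,
      k_mean = mean(ks, na.rm = TRUE),
      qc = list(
        arterial = arterial$status,
        range_available = !is.null(range),
        desaturation_fraction = desat,
        desaturation_ok = !is.na(desat) & desat >= 0.3 & desat <= 0.7,
        converged = !is.na(ks),
        n_converged = sum(!is.na(ks)),
        dropped_occlusions = attr(slopes, "dropped")
      ),
      slopes = slopes,
      range = range
    ),
    class = "oxcap_result"
  )
}

#' @export
print.oxcap_result <- function(x, ...) {
  ks <- vapply(x$fits, function(f) f$k, numeric(1))
  cat(sprintf(
    "<oxcap_result> k_mean = %.3f min^-1 from %d/%d converged fits (%s); arterial QC: %s\n",
    x$k_mean, x$qc$n_converged, length(x$fits),
    paste(sprintf("%.3f", ks), collapse = ", "), x$qc$arterial))
  invisible(x)
}
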