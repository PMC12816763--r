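# Shorter-than-device sample rates are used throughout: the count and step
# definitions are integrals and band-limited peak counts, invariant to the
# sampling rate once above the locomotor Nyquist.

test_that("accelerometer simulator honours its ground-truth contract", {
  # same seed -> identical stream
  s1 <- simulate_accel_stream(days = 1, bouts_per_day = 1, seed = 3,
                              sample_rate = 5)
  s2 <- simulate_accel_stream(days = 1, bouts_per_day = 1, seed = 3,
                              sample_rate = 5)
  expect_identical(s1$az, s2$az)

  # no bouts, full-day wear -> zero true steps
  s0 <- simulate_accel_stream(days = 1, bouts_per_day = 0, seed = 1,
                              sample_rate = 5)
  expect_equal(s0$truth$steps_by_day$steps, 0)

  # one 600-step bout at 100 steps/min -> 600 steps over 6 min
  sb <- simulate_accel_stream(days = 1, bouts_per_day = 1, seed = 2,
                              sample_rate = 5)
  expect_equal(sb$truth$steps_by_day$steps, 600)

  # overlapping nonwear blocks are rejected
  expect_error(
    simulate_accel_stream(days = 1, seed = 1, sample_rate = 5,
                          nonwear_blocks = list(c(0, 3600),
                                                c(1800, 3600))),
    "overlap")
})

test_that("stillness-based wear detection obeys the run-length rule", {
  fs <- 10
  mk <- function(mins_still, total_mins = 180) {
    n <- total_mins * 60 * fs
    set.seed(5)
    ax <- rnorm(n, 0, 0.02); ay <- rnorm(n, 0, 0.02)
    az <- 1 + rnorm(n, 0, 0.02)
    still_idx <- seq_len(mins_still * 60 * fs) + 60 * 60 * fs
    ax[still_idx] <- 0; ay[still_idx] <- 0; az[still_idx] <- 1
    accel_stream(ax, ay, az, sample_rate = fs)
  }
  # constant gravity for 2 h -> those epochs nonworn
  worn <- detect_wear(mk(120))
  expect_false(any(worn[61:180]))
  expect_true(all(worn[1:60]))
  # 59-min still block inside an active day stays worn (below run length)
  worn59 <- detect_wear(mk(59))
  expect_true(all(worn59))
  # empty stream -> empty flags
  expect_length(detect_wear(accel_stream(numeric(0), numeric(0),
                                         numeric(0), sample_rate = fs)), 0)
})

test_that("VMU matches the closed-form rectified integral of a sinusoid", {
  fs <- 50
  n <- 5 * 60 * fs
  t <- (seq_len(n) - 1) / fs
  x <- 0.3 * sin(2 * pi * 2 * t)
  st <- accel_stream(x, numeric(n), rep(1, n), sample_rate = fs)
  ep <- vmu_per_epoch(st)
  # rectified integral of A sin(2 pi f t) over 60 s = A * 2/pi * 60 g s
  expected <- 0.3 * (2 / pi) * 60 / 0.1
  expect_lt(max(abs(ep$vmu / expected - 1)), 0.01)

  # zero dynamic acceleration -> zero counts
  still <- accel_stream(numeric(n), numeric(n), rep(1, n),
                        sample_rate = fs)
  expect_lt(max(vmu_per_epoch(still)$vmu), 1e-8)

  # same signal on two axes scales the norm by sqrt(2); the gravity axis
  # is zeroed so filter edge transients on it cannot blur the identity
  base1 <- accel_stream(x, numeric(n), numeric(n), sample_rate = fs)
  base2 <- accel_stream(x, x, numeric(n), sample_rate = fs)
  expect_equal(vmu_per_epoch(base2)$vmu, sqrt(2) * vmu_per_epoch(base1)$vmu,
               tolerance = 1e-9)
})

test_that("VMU is invariant to axis permutation and sign flips", {
  sim <- simulate_accel_stream(days = 1, bouts_per_day = 1, seed = 8,
                               sample_rate = 10)
  # restrict to one hour around the bout to keep the check fast
  idx <- seq(9 * 3600 * 10, 10 * 3600 * 10)
  base <- accel_stream(sim$ax[idx], sim$ay[idx], sim$az[idx],
                       sample_rate = 10)
  perm <- accel_stream(sim$az[idx], -sim$ax[idx], sim$ay[idx],
                       sample_rate = 10)
  expect_equal(vmu_per_epoch(base)$vmu, vmu_per_epoch(perm)$vmu,
               tolerance = 1e-8)
})

test_that("step counting recovers the simulated bout and is additive", {
  one <- simulate_accel_stream(days = 1, bouts_per_day = 0, seed = 3,
                               sample_rate = 25,
                               bout_starts_s = 10 * 3600)
  n1 <- length(step_events(one))
  expect_lt(abs(n1 / 600 - 1), 0.02)

  # nonworn (nonwear all day) -> zero steps
  nw <- simulate_accel_stream(
    days = 1, bouts_per_day = 0, seed = 4, sample_rate = 25,
    nonwear_blocks = list(c(0, 86400)))
  expect_equal(sum(count_steps(nw)$steps), 0)

  # two identical, well-separated bouts double the single-bout count
  two <- simulate_accel_stream(days = 1, bouts_per_day = 0, seed = 3,
                               sample_rate = 25,
                               bout_starts_s = c(10 * 3600, 14 * 3600))
  n2 <- length(step_events(two))
  expect_equal(n2, 2 * n1, tolerance = 0.01)
})

test_that("day validity and compliance boundaries are exact", {
  d <- day_records(date = as.Date("2026-01-05") + 0:1,
                   daytime_wear_h = c(8.0, 7.9),
                   steps = c(5000, 4000), mean_vmu = c(400, 300))
  expect_identical(d$valid, c(TRUE, FALSE))

  days7 <- day_records(date = as.Date("2026-01-05") + 0:6,
                       daytime_wear_h = c(9, 9, 9, 9, 2, 2, 2),
                       steps = 1000 * (1:7), mean_vmu = rep(100, 7))
  s4 <- summarize_activity(days7)
  expect_true(s4$compliant)
  expect_equal(s4$n_valid_days, 4)
  # means over valid days only
  expect_equal(s4$steps_per_day, mean(1000 * (1:4)))

  days3 <- days7
  days3$daytime_wear_h[4] <- 7.99
  s3 <- summarize_activity(days3)
  expect_false(s3$compliant)
  expect_equal(s3$n_valid_days, 3)

  # all days identical -> summary means equal the daily values
  same <- day_records(date = as.Date("2026-01-05") + 0:4,
                      daytime_wear_h = rep(10, 5), steps = rep(4321, 5),
                      mean_vmu = rep(321, 5))
  ss <- summarize_activity(same)
  expect_equal(ss$steps_per_day, 4321)
  expect_equal(ss$vmu_per_min, 321)

  # zero valid days -> undefined means (explicit NA, not zero)
  none <- day_records(date = as.Date("2026-01-05"), daytime_wear_h = 2,
                      steps = 100, mean_vmu = 10)
  sn <- summarize_activity(none)
  expect_false(sn$compliant)
  expect_true(is.na(sn$steps_per_day))
  expect_true(is.na(sn$vmu_per_min))
})

test_that("validity filtering is idempotent and order-independent", {
  set.seed(11)
  d <- day_records(date = as.Date("2026-01-05") + 0:9,
                   daytime_wear_h = runif(10, 4, 14),
                   steps = rpois(10, 5000), mean_vmu = runif(10, 50, 600))
  s_once <- summarize_activity(d)
  s_perm <- summarize_activity(d[sample(10), ])
  expect_equal(s_once, s_perm)
  # idempotence: summarising the valid subset gives the same means
  s_valid <- summarize_activity(d[d$valid, ])
  expect_equal(s_valid$steps_per_day, s_once$steps_per_day)
})

test_that("a 16-h nonwear block invalidates a 24-h day", {
  sim <- simulate_accel_stream(days = 1, bouts_per_day = 1, seed = 4,
                               sample_rate = 10,
                               nonwear_blocks = list(c(0, 16 * 3600)))
  d <- activity_days(sim)
  expect_lt(d$daytime_wear_h, 8)
  expect_false(d$valid)
})

test_that("whole-stream processing recovers simulated steps and VMU truth", {
  sim <- simulate_accel_stream(days = 1, bouts_per_day = 2, seed = 6,
                               sample_rate = 25)
  d <- activity_days(sim)
  expect_true(d$valid)
  expect_lt(abs(d$steps / sim$truth$steps_by_day$steps - 1), 0.02)
  ep <- vmu_per_epoch(sim)
  tv <- sim$truth$epoch_vmu
  in_bout <- tv$vmu > 100
  expect_lt(max(abs(ep$vmu[in_bout] / tv$vmu[in_bout] - 1)), 0.05)
})
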