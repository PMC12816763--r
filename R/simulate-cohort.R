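#' Per-group covariate moments used by the cohort simulator
#'
#' Group-wise means/SDs (age, spirometry, diffusing capacity, oximetry,
#' smoking exposure, anthropometry, activity and questionnaire scores) and
#' category frequencies matching the study population the simulator
#' emulates: never smokers, normal-spirometry smokers (Controls), PRISm and
#' the four COPD severity stages.
#'
#' @return A data.frame, one row per group.
#' @export
muscle_group_moments <- function() {
  g <- c("never_smoker", "control", "prism", "gold1", "gold2", "gold3",
         "gold4")
  data.frame(
    group = g,
    n = c(26, 76, 21, 30, 40, 35, 13),
    age_m = c(59.4, 60.0, 64.0, 70.1, 65.7, 68.0, 65.2),
    age_sd = c(10.3, 8.7, 11.2, 9.6, 8.1, 8.0, 10.1),
    fev1_m = c(106.5, 101.0, 69.1, 92.9, 66.2, 40.0, 21.0),
    fev1_sd = c(13.8, 12.5, 10.9, 11.1, 10.0, 5.6, 4.3),
    ratio_m = c(0.81, 0.80, 0.76, 0.64, 0.60, 0.43, 0.29),
    ratio_sd = c(0.06, 0.05, 0.05, 0.06, 0.06, 0.10, 0.09),
    dlco_m = c(88.8, 80.1, 65.8, 75.5, 66.2, 44.3, 37.2),
    dlco_sd = c(10.8, 17.0, 13.2, 19.5, 24.1, 12.6, 14.4),
    spo2_m = c(98.7, 98.4, 97.1, 97.6, 97.4, 96.3, 94.5),
    spo2_sd = c(0.5, 1.1, 3.0, 2.2, 1.3, 2.3, 5.5),
    bmi_m = c(28.3, 28.6, 31.1, 26.6, 27.8, 27.7, 26.3),
    bmi_sd = c(4.4, 6.7, 5.7, 4.1, 5.3, 6.3, 7.2),
    packyr_m = c(0, 39.4, 43.6, 39.8, 52.7, 52.9, 41.9),
    packyr_sd = c(0, 19.8, 25.7, 18.4, 25.2, 20.9, 28.6),
    vmu_m = c(455, 438, 310, 420, 380, 232, 135),
    vmu_sd = c(190, 184, 150, 180, 170, 139, 73),
    steps_m = c(6100, 5938, 3599, 5500, 5000, 3328, 2037),
    steps_sd = c(3100, 3121, 1928, 3000, 2800, 2241, 1756),
    dppac_m = c(72.0, 65.3, 62.3, 65.7, 64.9, 52.5, 47.1),
    dppac_sd = c(13.1, 10.1, 8.0, 11.6, 10.5, 9.0, 14.1),
    sgrq_m = c(8, 22, 32, 24, 34, 48, 55),
    sgrq_sd = c(8, 15, 16, 15, 16, 15, 16),
    p_female = c(15, 42, 14, 17, 18, 18, 4) / c(26, 76, 21, 30, 40, 35, 13),
    p_aa = c(13, 50, 10, 8, 13, 12, 4) / c(26, 76, 21, 30, 40, 35, 13),
    p_current = c(0, 42 / 76, 10 / 21, 9 / 29, 13 / 40, 8 / 35, 0)
  )
}

#' Parameters of the generative cohort model
#'
#' The cohort simulator draws group-structured covariates and generates the
#' outcome from a known linear model on the log scale:
#' `log k = beta0 + beta_fev1 * FEV1%pred + beta_age * age +
#' beta_race * I(African American) + e`, `e ~ N(0, sigma^2)`, `k = exp(log k)`.
#' The default coefficients are the multivariable estimates used as
#' simulation ground truth throughout the package. When `beta0` is NULL it
#' is solved so that the Controls-group mean of k equals
#' `control_mean_k` given the Controls covariate means (lognormal mean
#' correction included).
#'
#' @param n Number of participants (default 241).
#' @param beta_fev1 Effect per FEV1 %%predicted unit on log k
#'   (default 0.0045).
#' @param beta_age Effect per year of age (default -0.0102).
#' @param beta_race Effect of African American race (default -0.1059).
#' @param beta0 Intercept of log k, or NULL to calibrate to
#'   `control_mean_k`.
#' @param sigma Residual SD of log k (> 0); the default 0.29 gives a
#'   population R-squared of about 0.26 for the generative model under the
#'   default covariate moments.
#' @param missing_rate Fraction of values set missing completely at random
#'   in the missable covariates (0 <= rate < 1).
#' @param control_mean_k Target Controls-group mean of k (min^-1);
#'   default 1.67.
#' @param covariate_moments Per-group moments table; default
#'   [muscle_group_moments()].
#' @param seed Integer seed.
#' @return An object of class `cohort_sim_params`.
#' @export
cohort_sim_params <- function(n = 241,
                              beta_fev1 = 0.0045,
                              beta_age = -0.0102,
                              beta_race = -0.1059,
                              beta0 = NULL,
                              sigma = 0.29,
                              missing_rate = 0.05,
                              control_mean_k = 1.67,
                              covariate_moments = muscle_group_moments(),
                              seed = 1L) {
  stopifnot(sigma > 0, missing_rate >= 0, missing_rate < 1, n >= 1)
  if (is.null(beta0)) {
    cm <- covariate_moments[covariate_moments$group == "control", ]
    beta0 <- log(control_mean_k) -
      (beta_fev1 * cm$fev1_m + beta_age * cm$age_m + beta_race * cm$p_aa) -
      sigma^2 / 2
  }
  structure(
    list(n = as.integer(n), beta_fev1 = beta_fev1, beta_age = beta_age,
         beta_race = beta_race, beta0 = beta0, sigma = sigma,
         missing_rate = missing_rate,
         covariate_moments = covariate_moments, seed = as.integer(seed)),
    class = "cohort_sim_params"
  )
}

# truncated normal draw via inverse-CDF
rtnorm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  if (sd <= 0) return(pmin(hi, pmax(lo, rep(mean, n))))
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

#' Simulate a cohort with a known generative model on log(k)
#'
#' Group sizes follow the moment table's proportions (largest-remainder
#' allocation); covariates are drawn per group with spirometry truncated to
#' each group's defining region so that [classify()] reproduces the
#' assigned label. Activity (VMU/min) is partially driven by FEV1 %%pred
#' within group, and steps, the activity questionnaire score and SGRQ are
#' in turn correlated with VMU — the confounding structure the sensitivity
#' analyses probe. Missingness is applied completely at random.
#'
#' @param params A [cohort_sim_params()] object.
#' @return A data.frame of class `cohort_table` with attribute `truth`
#'   (the generative coefficients, sigma and per-row linear predictor).
#' @export
simulate_cohort <- function(params) {
  stopifnot(inherits(params, "cohort_sim_params"))
  if (params$n < 6) {
    stop("n must be at least the number of model parameters + 2 (6)")
  }
  mom <- params$covariate_moments
  n <- params$n

  # largest-remainder allocation of n across groups
  target <- n * mom$n / sum(mom$n)
  n_g <- floor(target)
  rem <- n - sum(n_g)
  if (rem > 0) {
    o <- order(target - n_g, decreasing = TRUE)[seq_len(rem)]
    n_g[o] <- n_g[o] + 1
  }

  withr_seed(params$seed, function() {
    rows <- lapply(seq_len(nrow(mom)), function(gi) {
      m <- mom[gi, ]
      ng <- n_g[gi]
      if (ng == 0) return(NULL)
      grp <- m$group
      # spirometry truncated to the group's defining region
      lim <- switch(grp,
        never_smoker = ,
        control = list(fev1 = c(80, 150), ratio = c(0.70, 0.95)),
        prism = list(fev1 = c(25, 79.99), ratio = c(0.70, 0.95)),
        gold1 = list(fev1 = c(80, 130), ratio = c(0.35, 0.6999)),
        gold2 = list(fev1 = c(50, 79.99), ratio = c(0.30, 0.6999)),
        gold3 = list(fev1 = c(30, 49.99), ratio = c(0.15, 0.6999)),
        gold4 = list(fev1 = c(8, 29.99), ratio = c(0.10, 0.6999))
      )
      fev1 <- rtnorm(ng, m$fev1_m, m$fev1_sd, lim$fev1[1], lim$fev1[2])
      ratio <- rtnorm(ng, m$ratio_m, m$ratio_sd, lim$ratio[1], lim$ratio[2])
      age <- rtnorm(ng, m$age_m, m$age_sd, 40, 90)
      dlco <- rtnorm(ng, m$dlco_m, m$dlco_sd, 15, 140)
      spo2 <- rtnorm(ng, m$spo2_m, m$spo2_sd, 80, 100)
      bmi <- rtnorm(ng, m$bmi_m, m$bmi_sd, 16, 50)
      race <- ifelse(stats::runif(ng) < m$p_aa, "AA", "White")
      sex <- ifelse(stats::runif(ng) < m$p_female, "F", "M")
      smoking_status <- if (grp == "never_smoker") rep("never", ng) else
        ifelse(stats::runif(ng) < m$p_current, "current", "former")
      pack_years <- if (grp == "never_smoker") rep(0, ng) else
        rtnorm(ng, m$packyr_m, m$packyr_sd, 10, 130)
      smoked_within_2h <- smoking_status == "current" &
        stats::runif(ng) < 0.55
      # activity partially driven by lung function within group
      vmu <- rtnorm(ng, m$vmu_m + 2 * (fev1 - m$fev1_m),
                    m$vmu_sd * 0.9, 10, 1500)
      steps <- rtnorm(ng, m$steps_m + 9 * (vmu - m$vmu_m),
                      m$steps_sd * 0.55, 0, 25000)
      dppac <- rtnorm(ng, m$dppac_m + 0.025 * (vmu - m$vmu_m),
                      m$dppac_sd * 0.9, 0, 100)
      sgrq <- rtnorm(ng, m$sgrq_m - 0.02 * (vmu - m$vmu_m),
                     m$sgrq_sd, 0, 100)
      # predicted FEV1 (L) varies with age and sex plus independent
      # anthropometric scatter, so %pred and absolute litres remain
      # distinct dimensions (as with reference-equation predictions)
      pred_fev1 <- rtnorm(ng, 3.05 - 0.028 * (age - 63) +
                            0.55 * (sex == "M"), 0.5, 1.6, 5)
      fev1_l <- pmax(0.3, fev1 / 100 * pred_fev1)
      fvc_l <- fev1_l / ratio
      data.frame(
        group = grp, age = age, sex = sex, race = race,
        fev1_pct_pred = fev1, ratio = ratio, fev1_l = fev1_l,
        fvc_l = fvc_l, dlco_pct_pred = dlco, spo2 = spo2, bmi = bmi,
        pack_years = pack_years, smoking_status = smoking_status,
        smoked_within_2h = smoked_within_2h, vmu_min = vmu,
        steps_day = steps, dppac_total = dppac, sgrq_total = sgrq,
        hypertension = as.integer(stats::runif(ng) < 0.50),
        high_cholesterol = as.integer(stats::runif(ng) < 0.36),
        osteoarthritis = as.integer(stats::runif(ng) < 0.15),
        any_cancer = as.integer(stats::runif(ng) < 0.10),
        pancreatic_cancer = 0L
      )
    })
    dat <- do.call(rbind, rows)
    dat <- dat[sample.int(nrow(dat)), ]
    rownames(dat) <- NULL
    dat$id <- sprintf("P%04d", seq_len(nrow(dat)))
    dat$group <- factor(dat$group, levels = mom$group)

    lp <- params$beta0 +
      params$beta_fev1 * dat$fev1_pct_pred +
      params$beta_age * dat$age +
      params$beta_race * (dat$race == "AA")
    logk <- lp + stats::rnorm(nrow(dat), 0, params$sigma)
    dat$k <- exp(logk)

    missable <- c("dlco_pct_pred", "spo2", "bmi", "vmu_min", "steps_day",
                  "dppac_total", "sgrq_total")
    if (params$missing_rate > 0) {
      for (v in missable) {
        dat[[v]][stats::runif(nrow(dat)) < params$missing_rate] <- NA
      }
    }

    dat <- dat[c("id", setdiff(names(dat), "id"))]
    attr(dat, "truth") <- list(
      beta0 = params$beta0,
      betas = c(fev1_pct_pred = params$beta_fev1, age = params$beta_age,
                race_aa = params$beta_race),
      sigma = params$sigma,
      linear_predictor = lp
    )
    class(dat) <- c("cohort_table", "data.frame")
    dat
  })
}
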