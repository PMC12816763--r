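sim_design <- function(n = 300, seed = 1) {
  set.seed(seed)
  data.frame(x1 = rnorm(n), x2 = rnorm(n), x3 = rbinom(n, 1, 0.4),
             z1 = rnorm(n), z2 = rnorm(n), z3 = rnorm(n))
}

test_that("transform check prefers the scale matching the error structure", {
  d <- sim_design(500, 2)
  set.seed(3)
  lp <- 0.5 + 0.4 * d$x1
  # multiplicative error: log scale is the homoscedastic one
  d$k <- exp(lp + rnorm(500, 0, 0.3))
  res_mult <- log_transform_check(d, c("x1", "x2"))
  expect_identical(res_mult$selected, "log")
  expect_lt(abs(log(res_mult$log$spread_ratio)),
            abs(log(res_mult$raw$spread_ratio)))
  # additive error: raw scale preferred by the same index (intercept far
  # from zero keeps the outcome positive so both scales remain fittable)
  d$k <- 10 + 2 * d$x1 + rnorm(500, 0, 0.4)
  res_add <- log_transform_check(d, c("x1", "x2"))
  expect_identical(res_add$selected, "raw")
  # degenerate inputs
  d$k <- 1
  expect_error(log_transform_check(d, "x1"), "constant")
  d$k <- c(-1, rep(1, 499))
  expect_error(log_transform_check(d, "x1"), "positive")
})

test_that("prefilter applies missingness, zero-frequency and collinearity rules", {
  set.seed(4)
  n <- 200
  d <- data.frame(k = exp(rnorm(n)), a = rnorm(n), b = rnorm(n),
                  zero_flag = 0, dup = NA)
  d$dup <- d$a + rnorm(n, 0, 1e-4)     # |r| > 0.95 with a
  d$m31 <- rnorm(n); d$m31[seq_len(62)] <- NA   # 31% missing
  d$m30 <- rnorm(n); d$m30[seq_len(60)] <- NA   # exactly 30% missing
  tr <- prefilter(d, c("a", "b", "zero_flag", "dup", "m31", "m30"))
  expect_identical(tr$excluded_missing, "m31")
  expect_identical(tr$excluded_zero_frequency, "zero_flag")
  expect_identical(tr$excluded_collinear, "dup")
  expect_setequal(tr$kept, c("a", "b", "m30"))
  expect_true(all(c("m31", "zero_flag", "dup") %in% tr$log$variable))
})

test_that("univariate screen retains at the inclusive p <= alpha boundary", {
  d <- sim_design(150, 5)
  set.seed(6)
  d$k <- exp(0.3 * d$x1 + rnorm(150, 0, 0.5))
  scr <- univariate_screen(d, c("x1", "z1"), alpha = 0.2)
  expect_true("x1" %in% scr$screened_in)
  # boundary: alpha set exactly at a candidate's p keeps it (<= inclusive)
  p_z1 <- scr$results$p[scr$results$variable == "z1"]
  scr_at <- univariate_screen(d, c("x1", "z1"), alpha = p_z1)
  expect_true("z1" %in% scr_at$screened_in)
  scr_below <- univariate_screen(d, c("x1", "z1"),
                                 alpha = p_z1 * (1 - 1e-9))
  expect_false("z1" %in% scr_below$screened_in)
  # zero-variance candidate skipped with a log entry
  d$const <- 1
  scr_c <- univariate_screen(d, c("x1", "const"))
  expect_identical(scr_c$skipped, "const")
})

test_that("a true signal is reliably retained by the screen across replicates", {
  hits <- vapply(1:25, function(r) {
    co <- simulate_cohort(cohort_sim_params(n = 215, seed = 700 + r))
    d <- prepare_candidates(co)
    "age" %in% univariate_screen(d, c("age", "sex_f"))$screened_in
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("consensus importance filter finds planted signals and is deterministic", {
  set.seed(8)
  n <- 300
  d <- as.data.frame(matrix(rnorm(n * 13), n,
                            dimnames = list(NULL, paste0("n", 1:13))))
  d$s1 <- rnorm(n); d$s2 <- rnorm(n); d$s3 <- rbinom(n, 1, 0.5)
  d$k <- exp(0.5 * d$s1 - 0.4 * d$s2 + 0.3 * d$s3 + rnorm(n, 0, 0.4))
  cand <- setdiff(names(d), "k")
  imp <- importance_filter(d, cand, n_keep = 6, seed = 99)
  expect_true(all(c("s1", "s2", "s3") %in% imp$kept))
  expect_true(all(c("lasso", "random_forest", "xgboost") %in%
                    names(imp$cv_mse)))
  # fixed seed -> identical ranking across runs
  imp2 <- importance_filter(d, cand, n_keep = 6, seed = 99)
  expect_identical(imp$ranking, imp2$ranking)
  # n_keep larger than the candidate pool keeps all, with a warning
  expect_warning(all_kept <- importance_filter(d, c("s1", "s2"),
                                               n_keep = 5, seed = 1),
                 "keeping all")
  expect_setequal(all_kept$kept, c("s1", "s2"))
  expect_error(importance_filter(d, cand, n_keep = 3), "seed")
})

test_that("duplicated candidates get deterministic name-ordered tie-breaks", {
  set.seed(9)
  n <- 200
  d <- data.frame(k = exp(rnorm(n)), a_dup = rnorm(n))
  d$b_dup <- d$a_dup
  d$c_other <- rnorm(n)
  imp <- importance_filter(d, c("a_dup", "b_dup", "c_other"), n_keep = 3,
                           seed = 5)
  r <- imp$ranking
  # identical columns earn adjacent consensus positions, name-ordered
  expect_lt(which(r$variable == "a_dup"), which(r$variable == "b_dup"))
})

test_that("VIF filter matches closed forms and removes exact duplicates first", {
  set.seed(10)
  n <- 400
  d <- data.frame(k = exp(rnorm(n)))
  # orthogonalised predictors: all VIF ~ 1, none removed
  x <- qr.Q(qr(matrix(rnorm(n * 3), n)))
  d$o1 <- x[, 1]; d$o2 <- x[, 2]; d$o3 <- x[, 3]
  vf <- vif_filter(d, c("o1", "o2", "o3"))
  expect_setequal(vf$final_set, c("o1", "o2", "o3"))
  expect_true(all(vf$vif < 1.1))

  # bivariate closed form: r = 0.8 -> VIF = 1/(1-0.64) = 2.78 for both
  z <- rnorm(n)
  d$p1 <- z
  d$p2 <- 0.8 * scale(z)[, 1] + sqrt(1 - 0.64) * rnorm(n)
  vifs <- vif_filter(d, c("p1", "p2"), vif_cap = 10)$vif
  r2 <- cor(d$p1, d$p2)^2
  expect_equal(unname(vifs), rep(1 / (1 - r2), 2), tolerance = 1e-6)
  expect_equal(unname(vifs[1]), 2.78, tolerance = 0.5)

  # exact duplicate: infinite VIF, removed at the first iteration
  d$q1 <- rnorm(n); d$q2 <- d$q1; d$q3 <- rnorm(n)
  vf2 <- vif_filter(d, c("q1", "q2", "q3"))
  expect_identical(vf2$removed$variable[1], "q2")
  expect_true(is.infinite(vf2$removed$vif[1]))
  expect_setequal(vf2$final_set, c("q1", "q3"))
})

test_that("VIF filter cross-checks against the reference implementation", {
  co <- simulate_cohort(cohort_sim_params(n = 500, seed = 13))
  d <- prepare_candidates(co)
  vars <- c("age", "fev1_pct_pred", "bmi", "pack_years", "vmu_min")
  cc <- stats::complete.cases(d[c(vars, "k")])
  ours <- vif_filter(d[cc, ], vars, vif_cap = 1e9)$vif
  fit <- stats::lm(log(k) ~ age + fev1_pct_pred + bmi + pack_years +
                     vmu_min, d[cc, ])
  theirs <- car::vif(fit)
  expect_equal(unname(ours[names(theirs)]), unname(theirs),
               tolerance = 1e-6)
})

test_that("VIF filtering is order-invariant up to documented tie-breaks", {
  co <- simulate_cohort(cohort_sim_params(n = 400, seed = 14))
  d <- prepare_candidates(co)
  vars <- c("fev1_pct_pred", "ratio", "fvc_l", "fev1_l", "age")
  f1 <- vif_filter(d, vars)$final_set
  f2 <- vif_filter(d, rev(vars))$final_set
  expect_setequal(f1, f2)
})

test_that("multivariable fit recovers truth, degrades to null, guards singularities", {
  co <- simulate_cohort(cohort_sim_params(n = 2000, seed = 15, sigma = 0.1,
                                          missing_rate = 0))
  d <- prepare_candidates(co)
  truth <- attr(co, "truth")$betas
  fit <- fit_multivariable(d, c("fev1_pct_pred", "age", "race_aa"))
  cf <- fit$coefficients
  for (nm in names(truth)) {
    row <- cf[cf$term == nm, ]
    expect_lt(abs(row$estimate - truth[[nm]]) / row$se, 2)
  }
  expect_gt(fit$r_squared, 0.5)

  # permuted outcome: R^2 near zero
  set.seed(16)
  dp <- d
  dp$k <- sample(dp$k)
  fit0 <- fit_multivariable(dp, c("fev1_pct_pred", "age", "race_aa"))
  expect_lt(fit0$r_squared, 0.01)

  # empty set: intercept-only, R^2 = 0
  fit_i <- fit_multivariable(d, character(0))
  expect_equal(fit_i$r_squared, 0)
  expect_equal(nrow(fit_i$coefficients), 1)

  # singular design errors and names the aliased column
  ds <- d
  ds$age_copy <- ds$age
  expect_error(fit_multivariable(ds, c("age", "age_copy")),
               "age_copy")
})

test_that("effect translation reproduces the published conversions exactly", {
  t1 <- translate_effect(0.0045, -10)
  expect_equal(t1$percent_change_k, 100 * (exp(-0.045) - 1))
  expect_equal(round(t1$percent_change_k, 1), -4.4)
  t2 <- translate_effect(-0.0102, 10)
  expect_equal(round(t2$percent_change_k, 1), -9.7)
  expect_equal(translate_effect(0, 25)$percent_change_k, 0)
  # multiplicative inverse property:
  # (1 + p1/100)(1 + p2/100) = 1 for beta and -beta
  for (b in c(0.0045, -0.0102, 0.3)) {
    p1 <- translate_effect(b, 10)$percent_change_k
    p2 <- translate_effect(-b, 10)$percent_change_k
    expect_equal((1 + p1 / 100) * (1 + p2 / 100), 1, tolerance = 1e-12)
  }
})

test_that("stratified models recover stratum-specific effect patterns", {
  # construct a cohort where age matters only in normal spirometry and
  # FEV1 only in COPD (mirrors the stratified analysis design)
  hits <- vapply(1:10, function(r) {
    co <- simulate_cohort(cohort_sim_params(n = 1200, seed = 800 + r,
                                            missing_rate = 0))
    copd <- co$ratio < 0.7
    lp <- ifelse(copd, 0.006 * co$fev1_pct_pred, -0.012 * co$age)
    set.seed(900 + r)
    co$k <- exp(0.6 + lp + rnorm(nrow(co), 0, 0.25))
    sm <- stratified_models(co, c("fev1_pct_pred", "age"), min_n = 30)
    cf_c <- sm$copd$coefficients
    cf_n <- sm$normal$coefficients
    fev_sig_copd <- cf_c$p[cf_c$term == "fev1_pct_pred"] < 0.05 &&
      cf_c$estimate[cf_c$term == "fev1_pct_pred"] > 0
    age_sig_norm <- cf_n$p[cf_n$term == "age"] < 0.05 &&
      cf_n$estimate[cf_n$term == "age"] < 0
    fev_sig_copd && age_sig_norm
  }, logical(1))
  expect_gte(mean(hits), 0.9)

  # degenerate cases: tiny stratum skipped with warning
  co <- simulate_cohort(cohort_sim_params(n = 50, seed = 20))
  expect_warning(sm <- stratified_models(co, c("age"), min_n = 1000),
                 "skipped")
  expect_null(sm$copd)
})

test_that("VMU sensitivity analysis reports stable non-significance under confounding", {
  # VMU has zero direct effect but is correlated with FEV1 by
  # construction; at the study scale, with the other lung-function
  # proxies present, it stays non-significant in every leave-one-out fit
  fs <- c("fev1_pct_pred", "age", "race_aa", "spo2", "bmi",
          "dlco_pct_pred", "vmu_min", "dppac_total", "sgrq_total",
          "current_smoking")
  ok <- vapply(1:10, function(r) {
    co <- simulate_cohort(cohort_sim_params(n = 241, seed = 950 + r,
                                            missing_rate = 0))
    d <- prepare_candidates(co)
    sv <- sensitivity_vmu(d, fs)
    all(c(sv$full_p, sv$loo$vmu_p) > 0.05)
  }, logical(1))
  expect_gte(mean(ok), 0.9)

  # with a real activity effect, VMU is significant in the full model
  co <- simulate_cohort(cohort_sim_params(n = 1000, seed = 970,
                                          missing_rate = 0))
  set.seed(971)
  co$k <- co$k * exp(0.0012 * (co$vmu_min - mean(co$vmu_min)))
  d <- prepare_candidates(co)
  sv <- sensitivity_vmu(d, c("fev1_pct_pred", "age", "race_aa", "vmu_min"))
  expect_lt(sv$full_p, 0.05)

  # structure of the pairwise grid
  co2 <- simulate_cohort(cohort_sim_params(n = 600, seed = 980,
                                           missing_rate = 0))
  d2 <- prepare_candidates(co2)
  sv2 <- sensitivity_vmu(d2, c("fev1_pct_pred", "age", "vmu_min",
                               "dppac_total", "steps_day"))
  expect_true(all(c("fev1_pct_pred", "dppac_total", "steps_day") %in%
                    sv2$correlated))
  expect_true(!is.null(sv2$pairs))
  expect_true(all(c("vmu_p", "adj_r_squared") %in% names(sv2$pairs)))
})

test_that("the full pipeline composes and its trace is internally consistent", {
  co <- simulate_cohort(cohort_sim_params(n = 800, seed = 30))
  res <- run_correlates_pipeline(co, model_spec(seed = 31, cv_folds = 3),
                                 num_trees = 100, nrounds = 40)
  tr <- res$trace
  expect_true(all(res$final_set %in% tr$importance$kept))
  expect_true(all(tr$importance$kept %in% tr$screened_in))
  expect_identical(res$transform$selected, "log")
  expect_true(all(!tr$vif_removed$variable %in% res$final_set))
  expect_gte(res$fit$r_squared, 0)
})
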