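#' Specification of the correlates-of-k pipeline
#'
#' @param candidates Character vector of candidate variable names (columns
#'   of the prepared cohort; see [prepare_candidates()]). NULL means all
#'   numeric columns except the outcome.
#' @param screen_alpha Univariate retention threshold on p (inclusive);
#'   default 0.20.
#' @param missing_cap Maximum allowed missing fraction (exclusive);
#'   default 0.30.
#' @param vif_cap Variance-inflation-factor threshold; default 10.
#' @param n_keep Variables kept after importance filtering; default 13.
#' @param cv_folds Cross-validation folds for the importance voters;
#'   default 5.
#' @param collinear_r Absolute pairwise correlation above which the
#'   later-named variable is excluded before the univariate screen;
#'   default 0.95.
#' @param seed Integer seed for the stochastic voters.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(candidates = NULL, screen_alpha = 0.20,
                       missing_cap = 0.30, vif_cap = 10, n_keep = 13,
                       cv_folds = 5, collinear_r = 0.95, seed = 1L) {
  stopifnot(screen_alpha > 0, screen_alpha < 1, vif_cap > 1,
            missing_cap >= 0, missing_cap < 1, n_keep >= 1, cv_folds >= 2)
  structure(
    list(candidates = candidates, screen_alpha = screen_alpha,
         missing_cap = missing_cap, vif_cap = vif_cap, n_keep = n_keep,
         cv_folds = cv_folds, collinear_r = collinear_r,
         seed = as.integer(seed)),
    class = "model_spec"
  )
}

#' Derive numeric candidate columns from a cohort table
#'
#' Encodes the categorical fields of a simulated or assembled cohort as
#' numeric indicator candidates (race_aa, sex_f, current_smoking,
#' former_smoking) alongside the continuous covariates, keeping `k` and the
#' grouping/spirometry columns needed downstream.
#'
#' @param cohort A `cohort_table`.
#' @return A data.frame with `k` plus numeric candidate columns; attribute
#'   `candidates` lists them.
#' @export
prepare_candidates <- function(cohort) {
  stopifnot("k" %in% names(cohort))
  d <- data.frame(k = cohort$k)
  keep_numeric <- intersect(
    c("age", "fev1_pct_pred", "ratio", "fev1_l", "fvc_l", "dlco_pct_pred",
      "spo2", "bmi", "pack_years", "vmu_min", "steps_day", "dppac_total",
      "sgrq_total", "hypertension", "high_cholesterol", "osteoarthritis",
      "any_cancer", "pancreatic_cancer"),
    names(cohort))
  for (v in keep_numeric) d[[v]] <- as.numeric(cohort[[v]])
  if ("race" %in% names(cohort)) {
    d$race_aa <- as.numeric(cohort$race == "AA")
  }
  if ("sex" %in% names(cohort)) d$sex_f <- as.numeric(cohort$sex == "F")
  if ("smoking_status" %in% names(cohort)) {
    d$current_smoking <- as.numeric(cohort$smoking_status == "current")
    d$former_smoking <- as.numeric(cohort$smoking_status == "former")
  }
  attr(d, "candidates") <- setdiff(names(d), "k")
  d
}

# residual heteroscedasticity index: ratio of residual SD in the top vs
# bottom fitted-value tertile; 1 = homoscedastic on this index.
spread_ratio <- function(fit) {
  f <- stats::fitted(fit)
  r <- stats::resid(fit)
  q <- stats::quantile(f, c(1 / 3, 2 / 3))
  lo <- r[f <= q[1]]
  hi <- r[f >= q[2]]
  stats::sd(hi) / stats::sd(lo)
}

normality_stat <- function(fit) {
  r <- stats::resid(fit)
  if (length(r) > 4999) r <- sample(r, 4999)
  s <- stats::shapiro.test(r)
  c(W = unname(s$statistic), p = s$p.value)
}

#' Compare raw- and log-scale outcome models on residual diagnostics
#'
#' Fits the outcome against `covariates` on the raw and natural-log scales
#' and reports, for each, the residual spread ratio across fitted-value
#' tertiles (heteroscedasticity index) and the Shapiro-Wilk statistic of
#' the residuals. The scale whose spread ratio is closer to 1 (smaller
#' |log spread ratio|) is selected; ties go to the log scale, the pipeline
#' default.
#'
#' @param data A data.frame containing `outcome` and the covariates.
#' @param covariates Character vector of covariate names.
#' @param outcome Outcome column name (default "k"); must be positive.
#' @return A list of class `transform_check`: `selected` ("log" or "raw"),
#'   `raw`, `log` (each with spread_ratio and shapiro stats).
#' @export
log_transform_check <- function(data, covariates, outcome = "k") {
  y <- data[[outcome]]
  keep <- stats::complete.cases(data[c(outcome, covariates)])
  data <- data[keep, ]
  y <- y[keep]
  if (any(y <= 0)) stop("outcome must be positive for the log transform")
  if (stats::var(y) == 0) stop("outcome is constant; diagnostics degenerate")
  fml <- stats::reformulate(covariates, response = "..y")
  d <- data[covariates]
  d$..y <- y
  fit_raw <- stats::lm(fml, data = d)
  d$..y <- log(y)
  fit_log <- stats::lm(fml, data = d)
  res <- list(
    raw = list(spread_ratio = spread_ratio(fit_raw),
               shapiro = normality_stat(fit_raw)),
    log = list(spread_ratio = spread_ratio(fit_log),
               shapiro = normality_stat(fit_log))
  )
  hl <- abs(log(res$log$spread_ratio))
  hr <- abs(log(res$raw$spread_ratio))
  res$selected <- if (hr < hl) "raw" else "log"
  class(res) <- "transform_check"
  res
}

#' Prefilter candidates on missingness, zero frequency and collinearity
#'
#' Drops candidates with a missing fraction strictly above `missing_cap`,
#' binary candidates with zero positive cases, and (pairwise) the
#' later-named member of any pair with |r| > `collinear_r`; every exclusion
#' is logged with its reason.
#'
#' @param data Prepared cohort data (see [prepare_candidates()]).
#' @param candidates Candidate names; default from the data attribute.
#' @param missing_cap Strict missingness cap; default 0.30.
#' @param collinear_r Pairwise collinearity cap; default 0.95.
#' @return A list of class `selection_trace` (partial): `kept`,
#'   `excluded_missing`, `excluded_zero_frequency`, `excluded_collinear`,
#'   `log` (data.frame variable/reason).
#' @export
prefilter <- function(data, candidates = attr(data, "candidates"),
                      missing_cap = 0.30, collinear_r = 0.95) {
  stopifnot(length(candidates) >= 1, all(candidates %in% names(data)))
  log_df <- data.frame(variable = character(0), reason = character(0))
  add_log <- function(v, r) {
    rbind(log_df, data.frame(variable = v, reason = r))
  }

  miss <- vapply(data[candidates],
                 function(x) mean(is.na(x)), numeric(1))
  excluded_missing <- names(miss)[miss > missing_cap]
  for (v in excluded_missing) {
    log_df <- add_log(v, sprintf("missing fraction %.3f > %.2f",
                                 miss[[v]], missing_cap))
  }
  kept <- setdiff(candidates, excluded_missing)

  is_binary <- vapply(data[kept], function(x) {
    u <- unique(x[!is.na(x)])
    length(u) <= 2 && all(u %in% c(0, 1))
  }, logical(1))
  zero_pos <- vapply(data[kept], function(x) {
    sum(x[!is.na(x)] != 0) == 0
  }, logical(1))
  excluded_zero <- kept[is_binary & zero_pos]
  for (v in excluded_zero) log_df <- add_log(v, "zero positive cases")
  kept <- setdiff(kept, excluded_zero)

  excluded_coll <- character(0)
  if (length(kept) >= 2) {
    cc <- suppressWarnings(
      stats::cor(data[kept], use = "pairwise.complete.obs"))
    cc[is.na(cc)] <- 0
    # keep the first-named member of each over-correlated pair
    for (i in seq_along(kept)) {
      vi <- kept[i]
      if (vi %in% excluded_coll) next
      for (j in seq_along(kept)) {
        if (j <= i) next
        vj <- kept[j]
        if (vj %in% excluded_coll) next
        if (abs(cc[vi, vj]) > collinear_r) {
          excluded_coll <- c(excluded_coll, vj)
          log_df <- add_log(vj, sprintf("|r| = %.3f with %s > %.2f",
                                        abs(cc[vi, vj]), vi, collinear_r))
        }
      }
    }
  }
  kept <- setdiff(kept, excluded_coll)

  structure(
    list(kept = kept, excluded_missing = excluded_missing,
         excluded_zero_frequency = excluded_zero,
         excluded_collinear = excluded_coll, log = log_df),
    class = "selection_trace"
  )
}

#' Univariate screen of candidates against log(k)
#'
#' One simple linear regression of `log(k)` per candidate over that
#' candidate's complete cases; candidates with p <= `alpha` (inclusive) are
#' retained. Zero-variance candidates are skipped with a log entry.
#'
#' @param data Prepared cohort data with a positive `k` column.
#' @param candidates Candidate names.
#' @param alpha Retention threshold (inclusive); default 0.20.
#' @return A list: `results` (data.frame variable/beta/se/p/n),
#'   `screened_in`, `skipped`.
#' @export
univariate_screen <- function(data, candidates, alpha = 0.20) {
  stopifnot("k" %in% names(data), all(data$k > 0, na.rm = TRUE))
  y <- log(data$k)
  skipped <- character(0)
  rows <- lapply(candidates, function(v) {
    x <- data[[v]]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 3 || stats::var(x[ok]) == 0) {
      skipped <<- c(skipped, v)
      return(NULL)
    }
    s <- summary(stats::lm(y[ok] ~ x[ok]))$coefficients
    data.frame(variable = v, beta = s[2, 1], se = s[2, 2], p = s[2, 4],
               n = sum(ok))
  })
  res <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(res) <- NULL
  list(results = res,
       screened_in = res$variable[res$p <= alpha],
       skipped = skipped)
}

#' Consensus importance filter (LASSO, random forest, gradient boosting)
#'
#' Three voters rank the screened candidates on the complete-case matrix:
#' an L1-penalised linear model (penalty by K-fold cross-validation;
#' ranking by standardised |coefficient| at the CV-optimal penalty), a
#' random forest (permutation importance) and a gradient-boosted tree
#' ensemble (gain importance). The consensus rank is the mean of the three
#' per-method ranks (ties broken by variable name) and the top `n_keep`
#' candidates are kept. Cross-validated MSE per voter is logged.
#'
#' @param data Prepared cohort data with positive `k`.
#' @param screened_in Candidate names entering the filter.
#' @param n_keep Number to keep (default 13); if larger than the candidate
#'   set, all are kept with a warning.
#' @param seed Integer seed (mandatory).
#' @param cv_folds K for cross-validation; default 5.
#' @param num_trees Random-forest trees; default 500.
#' @param nrounds Boosting rounds; default 200.
#' @return A list: `kept`, `ranking` (data.frame with per-method and
#'   consensus ranks), `cv_mse` (named numeric), `n_complete`.
#' @export
importance_filter <- function(data, screened_in, n_keep = 13, seed,
                              cv_folds = 5, num_trees = 500,
                              nrounds = 200) {
  if (missing(seed)) stop("seed is required for the importance filter")
  stopifnot(length(screened_in) >= 1)
  cc <- stats::complete.cases(data[c("k", screened_in)])
  x <- as.matrix(data[cc, screened_in, drop = FALSE])
  y <- log(data$k[cc])
  if (n_keep > length(screened_in)) {
    warning("n_keep exceeds the number of screened candidates; keeping all")
    n_keep <- length(screened_in)
  }

  withr_seed(seed, function() {
    # --- LASSO -----------------------------------------------------
    cvl <- glmnet::cv.glmnet(x, y, alpha = 1, nfolds = cv_folds,
                             standardize = TRUE)
    b <- as.numeric(stats::coef(cvl, s = "lambda.min"))[-1]
    sds <- apply(x, 2, stats::sd)
    lasso_score <- abs(b) * sds
    lasso_mse <- cvl$cvm[cvl$lambda == cvl$lambda.min]

    # --- random forest (permutation importance, OOB MSE) -----------
    rf <- ranger::ranger(
      x = x, y = y, num.trees = num_trees,
      importance = "permutation", num.threads = 1,
      seed = seed)
    rf_score <- rf$variable.importance[screened_in]
    rf_mse <- rf$prediction.error

    # --- gradient boosting (gain importance, CV RMSE) --------------
    dtrain <- xgboost::xgb.DMatrix(x, label = y)
    xgb_params <- list(objective = "reg:squarederror", max_depth = 3,
                       eta = 0.1, nthread = 1)
    cvb <- xgboost::xgb.cv(params = xgb_params, data = dtrain,
                           nrounds = nrounds, nfold = cv_folds,
                           verbose = 0)
    ev <- cvb$evaluation_log
    best_round <- which.min(ev$test_rmse_mean)
    xgb_mse <- ev$test_rmse_mean[best_round]^2
    bst <- xgboost::xgb.train(params = xgb_params, data = dtrain,
                              nrounds = best_round)
    imp <- xgboost::xgb.importance(model = bst)
    xgb_score <- stats::setNames(rep(0, length(screened_in)), screened_in)
    xgb_score[imp$Feature] <- imp$Gain

    # ranks: 1 = most important; deterministic name tie-break
    mk_rank <- function(s) {
      s <- stats::setNames(as.numeric(s), screened_in)
      o <- order(-s, screened_in)
      r <- integer(length(s))
      r[o] <- seq_along(s)
      r
    }
    r_lasso <- mk_rank(lasso_score)
    r_rf <- mk_rank(rf_score)
    r_xgb <- mk_rank(xgb_score)
    consensus <- (r_lasso + r_rf + r_xgb) / 3

    ranking <- data.frame(
      variable = screened_in, rank_lasso = r_lasso, rank_rf = r_rf,
      rank_xgb = r_xgb, consensus = consensus
    )
    ranking <- ranking[order(ranking$consensus, ranking$variable), ]
    rownames(ranking) <- NULL

    list(kept = ranking$variable[seq_len(n_keep)],
         ranking = ranking,
         cv_mse = c(lasso = lasso_mse, random_forest = rf_mse,
                    xgboost = xgb_mse),
         n_complete = sum(cc))
  })
}

#' Variance-inflation-factor exclusion
#'
#' Iteratively removes the highest-VIF variable while any VIF exceeds
#' `vif_cap`. `VIF_j = 1 / (1 - R2_j)` from regressing candidate j on the
#' remaining candidates (complete cases); perfect collinearity gives an
#' infinite VIF and is removed first. Ties are broken by removing the
#' later variable name.
#'
#' @param data Prepared cohort data.
#' @param subset Candidate names (>= 2).
#' @param vif_cap Threshold; default 10.
#' @return A list: `final_set`, `removed` (data.frame variable/vif), `vif`
#'   (final VIFs).
#' @export
vif_filter <- function(data, subset, vif_cap = 10) {
  stopifnot(length(subset) >= 2)
  cc <- stats::complete.cases(data[subset])
  d <- data[cc, subset, drop = FALSE]
  removed <- data.frame(variable = character(0), vif = numeric(0))

  compute_vifs <- function(vars) {
    vapply(vars, function(v) {
      fit <- stats::lm(stats::reformulate(setdiff(vars, v), response = v),
                       data = d)
      r2 <- summary(fit)$r.squared
      if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
    }, numeric(1))
  }

  vars <- subset
  repeat {
    if (length(vars) < 2) break
    vifs <- compute_vifs(vars)
    if (all(vifs <= vif_cap)) break
    worst <- max(vifs)
    cand <- names(vifs)[vifs == worst | (is.infinite(vifs) &
                                           is.infinite(worst))]
    drop_v <- sort(cand, decreasing = TRUE)[1]
    removed <- rbind(removed,
                     data.frame(variable = drop_v, vif = worst))
    vars <- setdiff(vars, drop_v)
  }
  list(final_set = vars, removed = removed,
       vif = if (length(vars) >= 2) compute_vifs(vars) else
         stats::setNames(rep(1, length(vars)), vars))
}

#' Multivariable linear model of log(k)
#'
#' Ordinary least squares of `log(k)` on the final variable set over
#' complete cases, with coefficient table, R-squared and numeric residual
#' diagnostics (Shapiro-Wilk, heteroscedasticity spread ratio, maximum
#' Cook's distance, maximum leverage).
#'
#' @param data Prepared cohort data with positive `k`.
#' @param final_set Variable names; empty gives the intercept-only fit.
#' @param warn_ratio Warn when complete cases < `warn_ratio` x variables;
#'   default 10.
#' @return A list of class `multivariable_fit`: `coefficients` (term,
#'   estimate, se, p, lower, upper), `r_squared`, `adj_r_squared`,
#'   `n_complete_cases`, `diagnostics`, `fit` (the lm object).
#' @export
fit_multivariable <- function(data, final_set, warn_ratio = 10) {
  stopifnot("k" %in% names(data))
  cc <- stats::complete.cases(data[c("k", final_set)])
  d <- data[cc, , drop = FALSE]
  d$..logk <- log(d$k)
  if (length(final_set)) {
    mm <- as.matrix(d[final_set])
    qr_rank <- qr(cbind(1, mm))$rank
    if (qr_rank < length(final_set) + 1) {
      fit0 <- stats::lm(
        stats::reformulate(final_set, response = "..logk"), data = d)
      bad <- names(which(is.na(stats::coef(fit0))))
      stop("singular design; aliased columns: ",
           paste(bad, collapse = ", "))
    }
    if (nrow(d) < warn_ratio * length(final_set)) {
      warning(sprintf("only %d complete cases for %d variables",
                      nrow(d), length(final_set)))
    }
    fml <- stats::reformulate(final_set, response = "..logk")
  } else {
    fml <- stats::as.formula("..logk ~ 1")
  }
  fit <- stats::lm(fml, data = d)
  s <- summary(fit)
  ci <- stats::confint(fit)
  coefs <- data.frame(
    term = rownames(s$coefficients),
    estimate = s$coefficients[, 1],
    se = s$coefficients[, 2],
    p = s$coefficients[, 4],
    lower = ci[, 1],
    upper = ci[, 2]
  )
  rownames(coefs) <- NULL
  diag <- list(
    shapiro = tryCatch(normality_stat(fit), error = function(e) c(W = NA,
                                                                  p = NA)),
    spread_ratio = tryCatch(spread_ratio(fit), error = function(e) NA),
    max_cooks = tryCatch(max(stats::cooks.distance(fit), na.rm = TRUE),
                         error = function(e) NA),
    max_leverage = tryCatch(max(stats::hatvalues(fit)),
                            error = function(e) NA)
  )
  structure(
    list(coefficients = coefs,
         r_squared = if (length(final_set)) s$r.squared else 0,
         adj_r_squared = s$adj.r.squared,
         n_complete_cases = nrow(d),
         diagnostics = diag, fit = fit),
    class = "multivariable_fit"
  )
}

#' @export
print.multivariable_fit <- function(x, ...) {
  cat(sprintf("<multivariable_fit> n = %d, R^2 = %.3f\n",
              x$n_complete_cases, x$r_squared))
  print(x$coefficients, digits = 3)
  invisible(x)
}

#' Translate a log-scale coefficient into a percent change in k
#'
#' Because the model is fit to log(k), effects are multiplicative on the
#' original scale: a change of `delta` units in the covariate multiplies k
#' by `exp(beta * delta)`, i.e. changes it by
#' `100 * (exp(beta * delta) - 1)` percent.
#'
#' @param beta Coefficient on log(k) per covariate unit.
#' @param delta Covariate change in its own units.
#' @param variable Optional variable name carried through.
#' @return A list of class `effect_translation`: `variable`, `delta`,
#'   `percent_change_k`.
#' @export
translate_effect <- function(beta, delta, variable = NA_character_) {
  structure(
    list(variable = variable, delta = delta,
         percent_change_k = 100 * (exp(beta * delta) - 1)),
    class = "effect_translation"
  )
}

#' @export
print.effect_translation <- function(x, ...) {
  cat(sprintf("<effect_translation> %s: delta %g -> %+.2f%% in k\n",
              if (is.na(x$variable)) "(coefficient)" else x$variable,
              x$delta, x$percent_change_k))
  invisible(x)
}

#' Stratified multivariable models by COPD status
#'
#' Fits the same final variable set separately in the COPD stratum
#' (FEV1/FVC < 0.70) and the normal-spirometry stratum (ratio >= 0.70 and
#' FEV1 >= 80%% predicted). Strata smaller than `min_n` are skipped with a
#' warning.
#'
#' @param cohort A `cohort_table` (needs `ratio`, `fev1_pct_pred`).
#' @param final_set Variable names (columns of the prepared data).
#' @param min_n Minimum stratum size; default 20.
#' @return A list with elements `copd` and `normal` (each a
#'   `multivariable_fit` or NULL).
#' @export
stratified_models <- function(cohort, final_set, min_n = 20) {
  d <- prepare_candidates(cohort)
  strata <- list(
    copd = cohort$ratio < 0.70,
    normal = cohort$ratio >= 0.70 & cohort$fev1_pct_pred >= 80
  )
  lapply(strata, function(sel) {
    sel <- sel & !is.na(sel)
    if (sum(sel) < min_n) {
      warning("stratum too small (", sum(sel), " < ", min_n, "); skipped")
      return(NULL)
    }
    vars <- final_set[vapply(final_set, function(v) {
      stats::var(d[[v]][sel], na.rm = TRUE) > 0
    }, logical(1))]
    fit_multivariable(d[sel, , drop = FALSE], vars, warn_ratio = 0)
  })
}

#' Sensitivity analysis for the activity variable (VMU/min)
#'
#' (i) Leave-one-out: each other member of the final set is removed in
#' turn, the model refit, and the VMU coefficient's p value recorded.
#' (ii) Correlate pairs: final-set members correlated with VMU/min
#' (|r| > `cor_threshold`) are identified, and the model refit with each
#' pair of them removed simultaneously, recording VMU's p and the adjusted
#' R-squared.
#'
#' @param data Prepared cohort data.
#' @param final_set Final variable set; must contain `vmu_var`.
#' @param vmu_var Name of the activity variable; default "vmu_min".
#' @param cor_threshold Correlation threshold for (ii); default 0.3.
#' @return A list of class `vmu_sensitivity`: `full_p`, `loo`
#'   (data.frame removed/vmu_p), `correlated`, `pairs` (data.frame
#'   removed_1/removed_2/vmu_p/adj_r_squared).
#' @export
sensitivity_vmu <- function(data, final_set, vmu_var = "vmu_min",
                            cor_threshold = 0.3) {
  stopifnot(vmu_var %in% final_set)
  vmu_p <- function(fit) {
    cf <- fit$coefficients
    cf$p[cf$term == vmu_var]
  }
  full <- fit_multivariable(data, final_set, warn_ratio = 0)
  others <- setdiff(final_set, vmu_var)

  loo <- do.call(rbind, lapply(others, function(v) {
    f <- fit_multivariable(data, setdiff(final_set, v), warn_ratio = 0)
    data.frame(removed = v, vmu_p = vmu_p(f))
  }))

  cors <- vapply(others, function(v) {
    suppressWarnings(stats::cor(data[[v]], data[[vmu_var]],
                                use = "pairwise.complete.obs"))
  }, numeric(1))
  correlated <- others[!is.na(cors) & abs(cors) > cor_threshold]

  pairs <- NULL
  if (length(correlated) >= 2) {
    cmb <- utils::combn(correlated, 2)
    pairs <- do.call(rbind, lapply(seq_len(ncol(cmb)), function(i) {
      rm2 <- cmb[, i]
      f <- fit_multivariable(data, setdiff(final_set, rm2),
                             warn_ratio = 0)
      data.frame(removed_1 = rm2[1], removed_2 = rm2[2],
                 vmu_p = vmu_p(f), adj_r_squared = f$adj_r_squared)
    }))
  }
  structure(
    list(full_p = vmu_p(full), loo = loo, correlated = correlated,
         pairs = pairs),
    class = "vmu_sensitivity"
  )
}

#' Run the full correlates-of-k pipeline
#'
#' Composes transform check, prefilter, univariate screen, consensus
#' importance filter, VIF exclusion and the final multivariable fit,
#' returning the complete selection trace.
#'
#' @param cohort A `cohort_table` with positive `k`.
#' @param spec A [model_spec()]; default spec if NULL.
#' @param ... Passed to [importance_filter()] (e.g. `num_trees`,
#'   `nrounds`).
#' @return A list of class `correlates_result`: `transform`, `trace`
#'   (prefilter + screen + importance + VIF), `univariate`, `final_set`,
#'   `fit`.
#' @export
run_correlates_pipeline <- function(cohort, spec = NULL, ...) {
  if (is.null(spec)) spec <- model_spec()
  d <- prepare_candidates(cohort)
  candidates <- spec$candidates
  if (is.null(candidates)) candidates <- attr(d, "candidates")

  pre <- prefilter(d, candidates, missing_cap = spec$missing_cap,
                   collinear_r = spec$collinear_r)
  transform <- log_transform_check(d, pre$kept)
  scr <- univariate_screen(d, pre$kept, alpha = spec$screen_alpha)
  imp <- importance_filter(d, scr$screened_in, n_keep = spec$n_keep,
                           seed = spec$seed, cv_folds = spec$cv_folds, ...)
  vf <- if (length(imp$kept) >= 2) {
    vif_filter(d, imp$kept, vif_cap = spec$vif_cap)
  } else list(final_set = imp$kept,
              removed = data.frame(variable = character(0),
                                   vif = numeric(0)),
              vif = numeric(0))
  fit <- fit_multivariable(d, vf$final_set, warn_ratio = 0)

  structure(
    list(
      transform = transform,
      trace = list(
        excluded_missing = pre$excluded_missing,
        excluded_zero_frequency = pre$excluded_zero_frequency,
        excluded_collinear = pre$excluded_collinear,
        screened_in = scr$screened_in,
        importance = imp,
        vif_removed = vf$removed,
        final_set = vf$final_set
      ),
      univariate = scr$results,
      final_set = vf$final_set,
      fit = fit
    ),
    class = "correlates_result"
  )
}

#' @export
print.correlates_result <- function(x, ...) {
  cat(sprintf(
    "<correlates_result> %d screened in -> %d after importance -> %d final (R^2 = %.3f, n = %d)\n",
    length(x$trace$screened_in), length(x$trace$importance$kept),
    length(x$final_set), x$fit$r_squared, x$fit$n_complete_cases))
  invisible(x)
}
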