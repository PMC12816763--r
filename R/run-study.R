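#' Configuration for an end-to-end synthetic study run
#'
#' All seeds must be explicit; [run_study()] refuses to run otherwise.
#'
#' @param out_dir Output directory for the report bundle.
#' @param seeds Named list with integer `cohort`, `nirs`, `activity` and
#'   `pipeline` entries.
#' @param n Cohort size; default 241.
#' @param n_nirs Participants for whom full NIRS recordings are simulated
#'   and re-estimated; default 12.
#' @param n_activity Participants for whom raw accelerometer streams are
#'   simulated and summarised; default 2.
#' @param activity_days Days of wear per simulated stream; default 7.
#' @param activity_sample_rate Stream sampling rate (Hz) for the synthetic
#'   activity stage; default 10 (the analysis is rate-invariant and a full
#'   week at 100 Hz is needlessly large for a report run).
#' @param nirs_noise_sd TSI noise for the NIRS stage; default 0.10.
#' @param pipeline_spec A [model_spec()]; default built from
#'   `seeds$pipeline`.
#' @return A list of class `run_config`.
#' @export
run_config <- function(out_dir, seeds, n = 241, n_nirs = 12,
                       n_activity = 2, activity_days = 7,
                       activity_sample_rate = 10, nirs_noise_sd = 0.10,
                       pipeline_spec = NULL) {
  cfg <- list(out_dir = out_dir, seeds = seeds, n = n, n_nirs = n_nirs,
              n_activity = n_activity, activity_days = activity_days,
              activity_sample_rate = activity_sample_rate,
              nirs_noise_sd = nirs_noise_sd,
              pipeline_spec = pipeline_spec)
  class(cfg) <- "run_config"
  validate_run_config(cfg)
  cfg
}

validate_run_config <- function(cfg) {
  need <- c("cohort", "nirs", "activity", "pipeline")
  if (is.null(cfg$seeds) || !all(need %in% names(cfg$seeds)) ||
      any(vapply(cfg$seeds[need], function(s) !is.numeric(s) || is.na(s),
                 logical(1)))) {
    stop("config must provide explicit integer seeds: ",
         paste(need, collapse = ", "))
  }
  if (is.null(cfg$out_dir)) stop("config must provide out_dir")
  invisible(cfg)
}

#' Read a run configuration from YAML
#' @param path YAML file with the [run_config()] fields.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(run_config, y[intersect(names(y), names(formals(run_config)))])
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

write_json_trace <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = 10,
                       pretty = TRUE, na = "null", force = TRUE)
}

#' Run the full synthetic study end to end
#'
#' Executes the pipeline stages in order — cohort simulation, NIRS
#' simulation + k estimation on a subsample, accelerometer simulation +
#' activity summary on a subsample, seven-group comparisons, and the
#' correlates-of-k regression pipeline with VMU sensitivity analysis —
#' writing study-style tables (group characteristics, univariate screen,
#' multivariable model), JSON stage traces and a run log into
#' `config$out_dir`. Reruns with the same configuration produce identical
#' numeric outputs.
#'
#' @param config A `run_config` (or a path to a YAML file of one).
#' @return Invisibly, a list with the in-memory stage results and the
#'   bundle file paths.
#' @export
run_study <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  validate_run_config(config)
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  log_lines <- c(
    sprintf("musclek run_study %s", as.character(utils::packageVersion("musclek"))),
    sprintf("started: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    sprintf("seeds: cohort=%d nirs=%d activity=%d pipeline=%d",
            config$seeds$cohort, config$seeds$nirs, config$seeds$activity,
            config$seeds$pipeline))

  # --- cohort ---------------------------------------------------------
  cohort <- stage("cohort", {
    simulate_cohort(cohort_sim_params(n = config$n,
                                      seed = config$seeds$cohort))
  })
  write_cohort_csv(cohort, file.path(out, "cohort.csv"))
  log_lines <- c(log_lines, sprintf("cohort: n=%d", nrow(cohort)))

  # --- NIRS subsample: simulate recordings at each participant's true k
  nirs_tab <- stage("nirs", {
    idx <- seq_len(min(config$n_nirs, nrow(cohort)))
    rows <- lapply(idx, function(i) {
      k_i <- min(5, max(0.3, cohort$k[i]))
      sched <- occlusion_schedule(seed = config$seeds$nirs + i)
      par <- nirs_sim_params(k_true = k_i,
                             noise_sd = config$nirs_noise_sd,
                             seed = config$seeds$nirs + i)
      rec <- simulate_nirs_recording(par, sched)
      res <- oxidative_capacity(rec)
      data.frame(id = cohort$id[i], k_true = k_i, k_hat = res$k_mean,
                 n_converged = res$qc$n_converged,
                 arterial_qc = res$qc$arterial)
    })
    do.call(rbind, rows)
  })
  utils::write.csv(nirs_tab, file.path(out, "nirs_validation.csv"),
                   row.names = FALSE)
  log_lines <- c(log_lines, sprintf(
    "nirs: %d recordings, median |rel err| = %.3f%%", nrow(nirs_tab),
    100 * stats::median(abs(nirs_tab$k_hat / nirs_tab$k_true - 1))))

  # --- activity subsample --------------------------------------------
  act_tab <- stage("activity", {
    idx <- seq_len(min(config$n_activity, nrow(cohort)))
    rows <- lapply(idx, function(i) {
      st <- simulate_accel_stream(
        days = config$activity_days, bouts_per_day = 3,
        seed = config$seeds$activity + i,
        sample_rate = config$activity_sample_rate)
      days <- activity_days(st)
      s <- summarize_activity(days)
      data.frame(id = cohort$id[i], n_valid_days = s$n_valid_days,
                 steps_per_day = s$steps_per_day,
                 vmu_per_min = s$vmu_per_min, compliant = s$compliant)
    })
    do.call(rbind, rows)
  })
  utils::write.csv(act_tab, file.path(out, "activity_summary.csv"),
                   row.names = FALSE)

  # --- group comparisons (characteristics table) ---------------------
  table1 <- stage("group_comparison", {
    outcomes <- intersect(c("k", "age", "fev1_pct_pred", "dlco_pct_pred",
                            "vmu_min", "steps_day"), names(cohort))
    rows <- lapply(outcomes, function(v) {
      gc <- compare_groups(cohort, v)
      st <- gc$group_stats
      eff <- merge(st, gc$contrasts, by = "group", all.x = TRUE)
      eff$outcome <- v
      eff$overall_p <- gc$overall$p
      eff$reported <- gc$report_effects
      eff
    })
    do.call(rbind, rows)
  })
  utils::write.csv(table1, file.path(out, "group_comparison.csv"),
                   row.names = FALSE)

  # --- correlates pipeline -------------------------------------------
  spec <- config$pipeline_spec
  if (is.null(spec)) spec <- model_spec(seed = config$seeds$pipeline)
  res <- stage("correlates", run_correlates_pipeline(cohort, spec))
  utils::write.csv(res$univariate, file.path(out, "univariate_screen.csv"),
                   row.names = FALSE)
  utils::write.csv(res$fit$coefficients,
                   file.path(out, "multivariable_model.csv"),
                   row.names = FALSE)
  write_json_trace(
    list(excluded_missing = res$trace$excluded_missing,
         excluded_zero_frequency = res$trace$excluded_zero_frequency,
         excluded_collinear = res$trace$excluded_collinear,
         screened_in = res$trace$screened_in,
         importance_ranking = res$trace$importance$ranking,
         cv_mse = as.list(res$trace$importance$cv_mse),
         vif_removed = res$trace$vif_removed,
         final_set = res$final_set,
         transform_selected = res$transform$selected,
         r_squared = res$fit$r_squared,
         n_complete_cases = res$fit$n_complete_cases),
    file.path(out, "selection_trace.json"))

  sens <- stage("sensitivity", {
    if ("vmu_min" %in% res$final_set) {
      d <- prepare_candidates(cohort)
      sensitivity_vmu(d, res$final_set)
    } else NULL
  })
  if (!is.null(sens)) {
    utils::write.csv(sens$loo, file.path(out, "sensitivity_vmu_loo.csv"),
                     row.names = FALSE)
    if (!is.null(sens$pairs)) {
      utils::write.csv(sens$pairs,
                       file.path(out, "sensitivity_vmu_pairs.csv"),
                       row.names = FALSE)
    }
  }

  log_lines <- c(log_lines, sprintf(
    "correlates: %d final variables, R^2 = %.3f",
    length(res$final_set), res$fit$r_squared), "done")
  writeLines(log_lines, file.path(out, "run_log.txt"))
  message(paste(log_lines, collapse = "\n"))

  invisible(list(cohort = cohort, nirs = nirs_tab, activity = act_tab,
                 group_comparison = table1, correlates = res,
                 sensitivity = sens,
                 files = list.files(out, full.names = TRUE)))
}
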