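#' Classify a participant by post-bronchodilator spirometry
#'
#' Seven mutually exclusive labels. Normal spirometry is FEV1/FVC >= 0.70
#' with FEV1 >= 80%% predicted: never smokers stay `never_smoker`, smokers
#' become `control`. A preserved ratio (>= 0.70) with FEV1 < 80%% predicted
#' is `prism`. FEV1/FVC < 0.70 is COPD, staged by FEV1 %%predicted:
#' `gold1` >= 80, `gold2` 50-79, `gold3` 30-49, `gold4` < 30 (the mild
#' stage's "> 80" band is read as including 80 so the four bands partition).
#'
#' @param ratio FEV1/FVC (0-1].
#' @param fev1_pct_pred FEV1 as %% of predicted.
#' @param smoking_status "never", "current" or "former".
#' @return Character vector of group labels (vectorised).
#' @export
classify <- function(ratio, fev1_pct_pred, smoking_status = "former") {
  n <- max(length(ratio), length(fev1_pct_pred), length(smoking_status))
  ratio <- rep_len(ratio, n)
  fev1 <- rep_len(fev1_pct_pred, n)
  smoking_status <- rep_len(smoking_status, n)
  if (any(!is.na(ratio) & (ratio <= 0 | ratio > 1))) {
    stop("ratio must be in (0, 1]")
  }
  if (any(is.na(ratio))) stop("spirometry (ratio) missing")
  if (any(ratio < 0.70 & is.na(fev1))) {
    stop("unstageable: FEV1/FVC < 0.70 with missing FEV1 %predicted")
  }
  if (any(is.na(fev1))) stop("FEV1 %predicted missing")

  out <- character(n)
  obstructed <- ratio < 0.70
  out[!obstructed & fev1 >= 80 & smoking_status == "never"] <- "never_smoker"
  out[!obstructed & fev1 >= 80 & smoking_status != "never"] <- "control"
  out[!obstructed & fev1 < 80] <- "prism"
  out[obstructed & fev1 >= 80] <- "gold1"
  out[obstructed & fev1 >= 50 & fev1 < 80] <- "gold2"
  out[obstructed & fev1 >= 30 & fev1 < 50] <- "gold3"
  out[obstructed & fev1 < 30] <- "gold4"
  out
}

#' Group labels in severity order
#' @return Character vector of the seven labels.
#' @export
group_levels <- function() {
  c("never_smoker", "control", "prism", "gold1", "gold2", "gold3", "gold4")
}

#' Welch's heteroscedastic one-way ANOVA
#'
#' Welch's F test (robust to unequal variances and group sizes), computed
#' via [stats::oneway.test()] with `var.equal = FALSE`.
#'
#' @param groups A named list of numeric samples (each n >= 2 with nonzero
#'   variance).
#' @return A list: `statistic` (F), `df` (numerator, denominator), `p`.
#' @export
welch_anova <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  groups <- lapply(groups, function(x) x[is.finite(x)])
  if (any(vapply(groups, length, integer(1)) < 2)) {
    stop("each group needs at least 2 observations")
  }
  if (any(vapply(groups, stats::var, numeric(1)) == 0)) {
    stop("a group has zero variance; Welch's ANOVA is undefined")
  }
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups),
                  vapply(groups, length, integer(1))))
  ht <- stats::oneway.test(y ~ g, var.equal = FALSE)
  list(statistic = unname(ht$statistic),
       df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Games-Howell post hoc contrasts against a reference group
#'
#' For each group g versus the reference: mean difference,
#' `SE = sqrt(s_g^2/n_g + s_r^2/n_r)`, Welch-Satterthwaite df, and a p value
#' from the studentized-range distribution with the total number of groups;
#' the 95%% CI is `diff +/- q_{alpha,k,df} * SE / sqrt(2)`.
#'
#' @param groups Named list of numeric samples (all groups entering the
#'   family, including the reference).
#' @param reference Name of the reference group (default "control").
#' @param conf_level Confidence level (default 0.95).
#' @return A data.frame: group, diff, se, df, p, lower, upper,
#'   indeterminate (n < 2 in either group).
#' @export
games_howell <- function(groups, reference = "control",
                         conf_level = 0.95) {
  stopifnot(is.list(groups), reference %in% names(groups))
  groups <- lapply(groups, function(x) x[is.finite(x)])
  k <- length(groups)
  ref <- groups[[reference]]
  others <- setdiff(names(groups), reference)

  out <- lapply(others, function(nm) {
    g <- groups[[nm]]
    if (length(g) < 2 || length(ref) < 2) {
      return(data.frame(group = nm, diff = NA_real_, se = NA_real_,
                        df = NA_real_, p = NA_real_, lower = NA_real_,
                        upper = NA_real_, indeterminate = TRUE))
    }
    vg <- stats::var(g) / length(g)
    vr <- stats::var(ref) / length(ref)
    se <- sqrt(vg + vr)
    df <- (vg + vr)^2 /
      (vg^2 / (length(g) - 1) + vr^2 / (length(ref) - 1))
    diff <- mean(g) - mean(ref)
    q <- abs(diff) / se * sqrt(2)
    p <- stats::ptukey(q, nmeans = k, df = df, lower.tail = FALSE)
    qc <- stats::qtukey(conf_level, nmeans = k, df = df)
    half <- qc * se / sqrt(2)
    data.frame(group = nm, diff = diff, se = se, df = df, p = p,
               lower = diff - half, upper = diff + half,
               indeterminate = FALSE)
  })
  do.call(rbind, out)
}

# log probability of a contingency table under fixed margins
# (multivariate hypergeometric / Fisher null)
log_table_prob <- function(tab) {
  sum(lgamma(rowSums(tab) + 1)) + sum(lgamma(colSums(tab) + 1)) -
    lgamma(sum(tab) + 1) - sum(lgamma(tab + 1))
}

#' Fisher's exact test with a Monte-Carlo p value
#'
#' Samples `reps` contingency tables with the observed margins fixed
#' (uniformly over label permutations, via [stats::r2dtable()]) and reports
#' `p = (1 + #{tables at most as probable as observed}) / (reps + 1)`.
#' Degenerate margins (all mass in one row or column) give p = 1.
#'
#' @param table Nonnegative integer matrix of counts.
#' @param reps Number of simulated tables (>= 1000); default 10000.
#' @param seed Integer seed (mandatory, for reproducibility).
#' @return The Monte-Carlo p value, with attribute `mc_se` (binomial
#'   standard error).
#' @export
fisher_exact_mc <- function(table, reps = 10000, seed) {
  if (missing(seed)) stop("seed is required for the Monte-Carlo p value")
  table <- as.matrix(table)
  if (any(table < 0) || any(table != round(table))) {
    stop("table must contain nonnegative integer counts")
  }
  if (reps < 1000) stop("reps must be at least 1000")
  rs <- rowSums(table)
  cs <- colSums(table)
  if (sum(rs > 0) < 2 || sum(cs > 0) < 2) {
    p <- 1
    attr(p, "mc_se") <- 0
    return(p)
  }
  obs <- log_table_prob(table)
  count <- withr_seed(seed, function() {
    sims <- stats::r2dtable(reps, rs, cs)
    sum(vapply(sims, log_table_prob, numeric(1)) <= obs + 1e-7)
  })
  p <- (1 + count) / (reps + 1)
  attr(p, "mc_se") <- sqrt(p * (1 - p) / (reps + 1))
  p
}

#' Bonferroni-controlled categorical post hoc contrasts
#'
#' Each non-reference group is compared with the reference in a 2-by-c
#' Fisher exact test; a contrast is significant iff its p value is strictly
#' below `alpha / comparisons`.
#'
#' @param table Counts matrix, groups in rows, categories in columns; row
#'   names identify groups.
#' @param reference Reference row name or index (default "control").
#' @param alpha Family significance level (default 0.05).
#' @param comparisons Number of comparisons in the family (default 6, the
#'   six reference-based contrasts of a seven-group design).
#' @return A data.frame: group, p, significant.
#' @export
posthoc_categorical <- function(table, reference = "control", alpha = 0.05,
                                comparisons = 6) {
  table <- as.matrix(table)
  if (is.character(reference)) {
    stopifnot(reference %in% rownames(table))
    ref_i <- which(rownames(table) == reference)
  } else ref_i <- reference
  others <- setdiff(seq_len(nrow(table)), ref_i)
  thr <- alpha / comparisons
  out <- lapply(others, function(i) {
    sub <- table[c(ref_i, i), , drop = FALSE]
    sub <- sub[, colSums(sub) > 0, drop = FALSE]
    p <- if (ncol(sub) < 2) 1 else stats::fisher.test(sub)$p.value
    data.frame(
      group = if (!is.null(rownames(table))) rownames(table)[i] else
        as.character(i),
      p = p, significant = p < thr)
  })
  do.call(rbind, out)
}

#' Percent difference of a group mean from a reference mean
#'
#' `100 * (1 - group_mean / reference_mean)`: positive when the group is
#' lower than the reference.
#'
#' @param reference_mean Reference group mean (> 0).
#' @param group_mean Comparison group mean.
#' @return Percent difference.
#' @export
compare_group_percent <- function(reference_mean, group_mean) {
  if (any(reference_mean <= 0)) stop("reference mean must be positive")
  100 * (1 - group_mean / reference_mean)
}

#' Group comparison of a continuous outcome across the seven groups
#'
#' Welch's ANOVA overall test plus Games-Howell contrasts versus the
#' reference group; effect sizes are reported only when the overall test is
#' significant (the contrasts are computed regardless and flagged).
#'
#' @param cohort A `cohort_table` (or data.frame with a `group` column).
#' @param outcome Name of the outcome column.
#' @param reference Reference group (default "control").
#' @param alpha Significance level for the overall gate (default 0.05).
#' @return A list of class `group_comparison`: `overall`
#'   (welch_anova result), `contrasts` (games_howell table),
#'   `report_effects` (overall significance gate), `group_stats`
#'   (n/mean/sd per group).
#' @export
compare_groups <- function(cohort, outcome, reference = "control",
                           alpha = 0.05) {
  stopifnot(outcome %in% names(cohort), "group" %in% names(cohort))
  y <- cohort[[outcome]]
  g <- as.character(cohort$group)
  keep <- is.finite(y) & !is.na(g)
  samples <- split(y[keep], g[keep])
  overall <- welch_anova(samples)
  contrasts <- games_howell(samples, reference = reference)
  stats_tab <- data.frame(
    group = names(samples),
    n = vapply(samples, length, integer(1)),
    mean = vapply(samples, mean, numeric(1)),
    sd = vapply(samples, stats::sd, numeric(1))
  )
  rownames(stats_tab) <- NULL
  structure(
    list(outcome = outcome, overall = overall, contrasts = contrasts,
         report_effects = overall$p < alpha, group_stats = stats_tab),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s: Welch F = %.2f, p = %.3g%s\n",
              x$outcome, x$overall$statistic, x$overall$p,
              if (x$report_effects) "" else " (effects not reported)"))
  if (x$report_effects) {
    print(x$contrasts, digits = 3)
  }
  invisible(x)
}
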