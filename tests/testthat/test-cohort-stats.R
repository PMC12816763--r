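test_that("spirometric classification follows the group definitions", {
  # values matching the PRISm column profile
  expect_identical(classify(0.76, 69.1, "former"), "prism")
  expect_identical(classify(0.29, 21, "former"), "gold4")
  # boundary: ratio exactly 0.70 with preserved FEV1 is control
  expect_identical(classify(0.70, 85, "current"), "control")
  expect_identical(classify(0.70, 85, "never"), "never_smoker")
  # staging bands
  expect_identical(classify(0.5, 85, "former"), "gold1")
  expect_identical(classify(0.5, 79.9, "former"), "gold2")
  expect_identical(classify(0.5, 50, "former"), "gold2")
  expect_identical(classify(0.5, 49.9, "former"), "gold3")
  expect_identical(classify(0.5, 30, "former"), "gold3")
  expect_identical(classify(0.5, 29.9, "former"), "gold4")
  expect_error(classify(0.5, NA, "former"), "unstageable")
  expect_error(classify(1.2, 80), "ratio")
})

test_that("classification is total and exclusive over a random spirometry grid", {
  set.seed(2)
  ratio <- runif(500, 0.2, 1)
  fev1 <- runif(500, 10, 130)
  status <- sample(c("never", "current", "former"), 500, replace = TRUE)
  lab <- classify(ratio, fev1, status)
  expect_true(all(lab %in% group_levels()))
  expect_true(all(nchar(lab) > 0))
  # exclusivity: recomputing flips nothing and each case maps to one label
  expect_identical(lab, classify(ratio, fev1, status))
})

test_that("welch_anova matches the pooled t-test in the equal-variance limit", {
  set.seed(3)
  x <- rnorm(40); y <- rnorm(40, 0.4)
  wa <- welch_anova(list(a = x, b = y))
  wt <- stats::t.test(x, y, var.equal = FALSE)
  expect_equal(wa$p, wt$p.value, tolerance = 1e-6)
  # identical groups: F = 0, p = 1
  z <- rnorm(20)
  w0 <- welch_anova(list(a = z, b = z))
  expect_equal(w0$statistic, 0)
  expect_equal(w0$p, 1)
  expect_error(welch_anova(list(a = rep(1, 5), b = rnorm(5))),
               "zero variance")
  expect_error(welch_anova(list(a = 1, b = rnorm(5))), "at least 2")
})

test_that("games_howell reduces to the Welch t-test for two groups", {
  set.seed(4)
  a <- rnorm(25, 0, 1.5); b <- rnorm(35, 0.6, 0.8)
  gh <- games_howell(list(control = a, g = b), reference = "control")
  wt <- stats::t.test(b, a)
  # with k = 2 the studentized range is sqrt(2) x t, so the p values agree
  expect_equal(gh$p, wt$p.value, tolerance = 1e-3)
  expect_equal(gh$diff, mean(b) - mean(a))
  expect_true(gh$lower < gh$diff && gh$diff < gh$upper)
})

test_that("games_howell p is monotone in |mean difference| at fixed spread", {
  set.seed(5)
  base <- rnorm(30)
  groups <- list(control = base, g1 = base + 0.2, g2 = base + 0.5,
                 g3 = base + 0.9)
  gh <- games_howell(groups)
  # same SE/df across contrasts by construction; larger shift, smaller p
  expect_true(all(diff(gh$p[order(abs(gh$diff))]) <= 0))
  # identical groups give diff 0, p ~ 1, CI symmetric about 0
  gh0 <- games_howell(list(control = base, same = base))
  expect_equal(gh0$diff, 0)
  expect_equal(gh0$p, 1, tolerance = 1e-12)
  expect_equal(gh0$lower, -gh0$upper)
  # undersized group flagged indeterminate
  ghna <- games_howell(list(control = base, tiny = 1))
  expect_true(ghna$indeterminate)
})

test_that("games_howell brackets the reference age contrast at the emulated group sizes", {
  set.seed(6)
  sims <- t(replicate(300, {
    ctrl <- rnorm(76, 60.0, 8.7)
    g1 <- rnorm(30, 70.1, 9.6)
    unlist(games_howell(list(control = ctrl, gold1 = g1))[
      c("diff", "lower", "upper")])
  }))
  expect_equal(mean(sims[, "diff"]), 10.1, tolerance = 0.15)
  # average CI width comparable to the printed [3.88, 16.30]
  expect_equal(mean(sims[, "upper"] - sims[, "lower"]), 16.3 - 3.88,
               tolerance = 0.08 * (16.3 - 3.88))
})

test_that("Monte-Carlo Fisher p agrees with exact enumeration on small tables", {
  tabs <- list(matrix(c(3, 1, 1, 3), 2), matrix(c(8, 2, 1, 9), 2),
               matrix(c(2, 5, 6, 1), 2), matrix(c(4, 4, 4, 4), 2))
  for (tab in tabs) {
    p <- fisher_exact_mc(tab, reps = 20000, seed = 11)
    exact <- enumerate_fisher_2x2(tab)
    expect_lt(abs(as.numeric(p) - exact), 2 * attr(p, "mc_se") + 1e-3)
    # the enumeration oracle itself agrees with the reference implementation
    expect_equal(exact, stats::fisher.test(tab)$p.value, tolerance = 1e-9)
  }
  # identical rows: p ~ 1
  expect_gt(as.numeric(fisher_exact_mc(matrix(c(5, 5, 5, 5), 2),
                                       reps = 2000, seed = 1)), 0.95)
  # degenerate margins
  expect_equal(as.numeric(fisher_exact_mc(matrix(c(5, 0, 3, 0), 2),
                                          reps = 2000, seed = 1)), 1)
  expect_error(fisher_exact_mc(matrix(c(1, 1, 1, 1), 2), reps = 10,
                               seed = 1), "reps")
  expect_error(fisher_exact_mc(matrix(c(1, 1, 1, 1), 2), reps = 2000),
               "seed")
})

test_that("doubling reps halves the Monte-Carlo standard error", {
  tab <- matrix(c(6, 3, 2, 7), 2)
  ps1 <- vapply(1:40, function(s) {
    as.numeric(fisher_exact_mc(tab, reps = 1000, seed = s))
  }, numeric(1))
  ps2 <- vapply(1:40, function(s) {
    as.numeric(fisher_exact_mc(tab, reps = 4000, seed = 100 + s))
  }, numeric(1))
  # quadrupling reps should halve the sd (sqrt law); allow wide MC slack
  expect_equal(sd(ps1) / sd(ps2), 2, tolerance = 0.5)
})

test_that("categorical post hoc contrasts honour the Bonferroni threshold strictly", {
  tab <- rbind(control = c(30, 46), g1 = c(10, 20), g2 = c(25, 5))
  res <- posthoc_categorical(tab)
  expect_identical(res$group, c("g1", "g2"))
  # each flag reproduces the strict p < alpha/6 rule on its own p value
  expect_identical(res$significant, res$p < 0.05 / 6)
  # a contrast with p just above the 0.05/6 threshold is not significant:
  # this table's exact p (~0.0092) sits between 0.05/6 and 0.05
  near <- rbind(control = c(39, 37), g = c(5, 25))
  p_near <- stats::fisher.test(matrix(near, 2))$p.value
  res_near <- posthoc_categorical(near)
  expect_identical(res_near$significant, p_near < 0.05 / 6)
  # a decisive contrast is significant
  strong <- rbind(control = c(40, 36), g = c(2, 28))
  expect_true(posthoc_categorical(strong)$significant)
  # all-null contrasts: nothing significant
  null_tab <- rbind(control = c(20, 20), a = c(20, 20), b = c(20, 20))
  expect_false(any(posthoc_categorical(null_tab)$significant))
})

test_that("percent contrasts reproduce the reported group deficits", {
  expect_equal(compare_group_percent(1.67, 1.37), 17.96, tolerance = 0.01)
  expect_equal(compare_group_percent(5938, 3328), 43.95, tolerance = 0.01)
  expect_equal(compare_group_percent(438, 232), 47.03, tolerance = 0.01)
  expect_equal(compare_group_percent(2, 2), 0)
  expect_error(compare_group_percent(0, 1), "positive")
})

test_that("compare_groups composes the overall test with reference contrasts", {
  co <- simulate_cohort(cohort_sim_params(n = 400, seed = 9))
  gc <- compare_groups(co, "k")
  expect_s3_class(gc, "group_comparison")
  expect_lt(gc$overall$p, 0.05)
  expect_setequal(gc$contrasts$group, setdiff(levels(co$group), "control"))
  # CI contains the point estimate everywhere
  ok <- !gc$contrasts$indeterminate
  expect_true(all(gc$contrasts$lower[ok] <= gc$contrasts$diff[ok] &
                    gc$contrasts$diff[ok] <= gc$contrasts$upper[ok]))
})
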