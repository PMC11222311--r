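counts <- reference_cohort_counts()

test_that("Pearson chi-square reproduces the published Table-1 statistics", {
  expect_equal(chisq_test(counts$mbg)$statistic, 23.478, tolerance = 0.01 / 23.478)
  expect_equal(chisq_test(counts$mag)$statistic, 28.223, tolerance = 0.01 / 28.223)
  expect_equal(chisq_test(counts$gli)$statistic, 17.786, tolerance = 0.01 / 17.786)
  expect_equal(chisq_test(counts$lage)$statistic, 11.165, tolerance = 0.01 / 11.165)
  expect_equal(chisq_test(counts$mbg)$df, 2)
  expect_equal(chisq_test(counts$mag)$df, 1)
})

test_that("chi-square basics: proportional rows, permutations, oracle", {
  prop <- rbind(c(100, 10), c(300, 30))
  expect_equal(chisq_test(prop)$statistic, 0)
  set.seed(51)
  tab <- matrix(rpois(6, 40) + 1, 3, 2)
  # textbook sum((O-E)^2/E)
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(chisq_test(tab)$statistic, sum((tab - E)^2 / E))
  expect_equal(chisq_test(tab[3:1, ])$statistic, chisq_test(tab)$statistic)
  expect_equal(chisq_test(tab[, 2:1])$statistic, chisq_test(tab)$statistic)
  expect_error(chisq_test(rbind(c(0, 0), c(3, 4))), "zero marginal")
  expect_error(chisq_test(matrix(5, 1, 2)), "2x2")
})

test_that("Mann-Whitney Z matches the normal-approximation test", {
  set.seed(52)
  x <- round(rnorm(80, 10, 2), 1)  # rounding induces ties
  y <- round(rnorm(120, 11, 2), 1)
  mw <- mann_whitney_z(x, y)
  ref <- wilcox.test(x, y, exact = FALSE, correct = TRUE)
  expect_equal(mw$p_value, ref$p.value, tolerance = 1e-10)
  expect_equal(mw$u, unname(ref$statistic))
  expect_lt(mw$z, 0)  # first group is smaller
  sym <- mann_whitney_z(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(sym$z, 0)
  expect_equal(sym$p_value, 1)
  expect_error(mann_whitney_z(rep(1, 5), rep(1, 5)), "tied")
})

test_that("logistic engine reproduces the published unadjusted MAG estimate", {
  d <- expand_counts(counts$mag)
  f <- fit_logistic(outcome ~ exposure, d)
  row <- f$table[f$table$term == "exposurehigh", ]
  expect_equal(row$or, 2.388, tolerance = 0.001 / 2.388)
  expect_equal(row$ci_low, 1.719, tolerance = 0.01 / 1.719)
  expect_equal(row$ci_high, 3.319, tolerance = 0.01 / 3.319)
})

test_that("2x2 logistic equals the cross-product closed form", {
  set.seed(53)
  for (i in 1:10) {
    cc <- matrix(rpois(4, 80) + 5, 2)
    d <- expand_counts(cc, levels = c("low", "high"))
    f <- fit_logistic(outcome ~ exposure, d)
    row <- f$table[f$table$term == "exposurehigh", ]
    or_oracle <- (cc[1, 1] * cc[2, 2]) / (cc[1, 2] * cc[2, 1])
    expect_equal(row$or, or_oracle, tolerance = 1e-6)
    expect_equal(row$se, sqrt(sum(1 / cc)), tolerance = 1e-6)
  }
  # outcome independent of a balanced exposure: OR exactly 1
  bal <- rbind(c(50, 20), c(50, 20))
  f <- fit_logistic(outcome ~ exposure, expand_counts(bal))
  expect_equal(f$table$or[2], 1, tolerance = 1e-9)
})

test_that("logistic engine flags separation and rank deficiency", {
  d <- data.frame(outcome = c(rep(0, 20), rep(1, 20)),
                  x = c(rep(0, 20), rep(1, 20)))
  expect_error(fit_logistic(outcome ~ x, d), "separation")
  d2 <- data.frame(outcome = rbinom(40, 1, 0.4), a = rnorm(40))
  d2$b <- d2$a
  expect_error(fit_logistic(outcome ~ a + b, d2), "aliased.*b")
})

test_that("the model ladder reproduces published unadjusted class ORs", {
  d <- expand_counts(counts$traj_class)
  d$outcome <- d$outcome
  names(d)[1] <- "traj_class"
  lad <- run_model_ladder(d, "traj_class", models = 1)
  expect_equal(lad$or[lad$level == "class4"], 3.712,
               tolerance = 0.001 / 3.712)
  expect_equal(lad$or[lad$level == "class3"], 4.102,
               tolerance = 0.001 / 4.102)
  expect_equal(lad$or[lad$level == "class2"], 0.960,
               tolerance = 0.001 / 0.960)
})

test_that("ladder specifications are nested and Model 1 is unadjusted", {
  for (m in 2:5) {
    expect_true(all(model_spec(m - 1) %in% model_spec(m)))
  }
  expect_length(model_spec(1), 0)
  expect_error(model_spec(6), "1..5")
})

test_that("fully adjusted ladder recovers a planted exposure effect", {
  cfg <- sim_config(n_patients = 8000, seed = 54,
                    outcome_coefficients = c(
                      intercept = -2.6, mag_high = log(2),
                      age = 0.03, sofa = 0.1))
  sim <- generate_cohort(cfg)
  idx <- stratify_indices(compute_indices(sim$glucose), "median")
  tab <- build_analysis_table(sim$records, idx)
  lad <- run_model_ladder(tab, "mag_cat", models = c(1, 5))
  fit5 <- attr(lad, "fits")$model5
  row <- fit5$table[fit5$table$term == "mag_cathigh", ]
  expect_lt(abs(row$estimate - log(2)), 3 * row$se)
  # empty adjustment set added changes nothing
  lad1 <- run_model_ladder(tab, "mag_cat", models = 1)
  f1 <- fit_logistic(outcome ~ mag_cat, tab)
  expect_equal(lad1$or[1], f1$table$or[2], tolerance = 1e-12)
})

test_that("univariate screening keeps real signals and rejects noise at alpha", {
  set.seed(55)
  n <- 4000
  x <- rnorm(n)
  p <- plogis(-2 + 1.2 * x)
  d <- data.frame(outcome = rbinom(n, 1, p), strong = x,
                  constant = 1)
  noise <- matrix(rnorm(n * 300), n)
  colnames(noise) <- paste0("z", 1:300)
  d <- cbind(d, noise)
  expect_warning(sc <- screen_covariates(d, c("strong", "constant")),
                 "constant")
  expect_true(sc$selected[sc$candidate == "strong"])
  scn <- screen_covariates(d, paste0("z", 1:300))
  rate <- mean(scn$selected)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / 300))
})

test_that("describe_cohort mirrors the two-group table layout", {
  d <- expand_counts(counts$mbg)
  names(d)[1] <- "mbg_stratum"
  d$pod <- d$outcome
  d$age <- rnorm(nrow(d), 68 + 2 * d$outcome, 5)
  rep_ <- describe_cohort(d, "pod", continuous = "age",
                          categorical = "mbg_stratum")
  expect_equal(rep_$categorical$chisq, 23.478, tolerance = 0.01 / 23.478)
  expect_gt(rep_$continuous$z, 0)  # POD group shifted upward
  expect_lt(rep_$continuous$p_value, 0.05)
})

test_that("subgroup analysis drops the stratifier and partitions the cohort", {
  cfg <- sim_config(n_patients = 6000, seed = 56,
                    outcome_coefficients = c(
                      intercept = -2.8, mag_high = log(1.5),
                      "mag_high:sepsis" = log(2)))
  sim <- generate_cohort(cfg)
  idx <- stratify_indices(compute_indices(sim$glucose), "median")
  tab <- build_analysis_table(sim$records, idx)
  sg <- subgroup_analysis(tab, "mag_cat", "sepsis")
  expect_equal(sum(sg$n), nrow(tab))
  # planted effects: OR 1.5 without sepsis, 3.0 with sepsis
  lo <- sg[sg$stratum == "non-sepsis", ]
  hi <- sg[sg$stratum == "sepsis", ]
  expect_lt(abs(log(lo$or) - log(1.5)),
            3 * (log(lo$ci_high) - log(lo$or)) / 1.96)
  expect_lt(abs(log(hi$or) - log(3)),
            3 * (log(hi$ci_high) - log(hi$or)) / 1.96)
  # age split partitions and drops age from the adjustment set
  sga <- subgroup_analysis(tab, "mag_cat", "age")
  expect_equal(sum(sga$n), nrow(tab))
  # zero-event stratum flagged, not an exception
  tab0 <- tab
  tab0$outcome[tab0$sepsis == 1] <- 0
  sg0 <- subgroup_analysis(tab0, "mag_cat", "sepsis")
  expect_equal(sg0$note[sg0$stratum == "sepsis"], "inestimable")
})
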