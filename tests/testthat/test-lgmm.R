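test_that("relative entropy matches the normalized Shannon double sum", {
  sharp <- diag(3)[c(1, 2, 3, 1), ]
  expect_equal(compute_entropy(sharp), 1)
  flat <- matrix(1 / 4, 6, 4)
  expect_equal(compute_entropy(flat), 0)
  set.seed(31)
  W <- matrix(rgamma(50 * 3, 1), 50)
  W <- W / rowSums(W)
  oracle <- 1 - sum(vapply(seq_len(50), function(i)
    sum(-W[i, ] * log(W[i, ])), numeric(1))) / (50 * log(3))
  expect_equal(compute_entropy(W), oracle)
  expect_equal(compute_entropy(matrix(1, 10, 1)), 1)
})

test_that("EM log-likelihood is non-decreasing over iterations", {
  set.seed(32)
  cfg <- sim_config(n_patients = 300, seed = 32)
  sim <- generate_cohort(cfg)
  for (k in c(2, 3)) {
    f <- fit_lgmm(sim$glucose, K = k, seed = 32, n_restarts = 2)
    expect_true(all(diff(f$ll_trace) >= -1e-6 * (1 + abs(f$ll_trace[-1]))))
  }
})

test_that("the one-class fit equals direct mixed-model maximization", {
  skip_if_not_installed("lme4")
  set.seed(33)
  cfg <- sim_config(n_patients = 120, seed = 33)
  sim <- generate_cohort(cfg)
  f <- fit_lgmm(sim$glucose, K = 1, n_restarts = 1, tol = 1e-12,
                max_iter = 5000)
  expect_equal(f$entropy, 1)
  g <- sim$glucose
  g$u <- (g$time_h - 12) / 12
  lm1 <- lme4::lmer(glucose_mgdl ~ u + I(u^2) + (1 | patient_id),
                    data = g, REML = FALSE)
  expect_lt(abs(f$loglik - as.numeric(logLik(lm1))), 1e-4)
  # curve coefficients agree with the GLS solution on the hour scale
  fx <- lme4::fixef(lm1)
  hour <- c(fx[1] - fx[2] + fx[3], fx[2] / 12 - fx[3] / 6, fx[3] / 144)
  expect_equal(unname(f$coefficients[, 1]), unname(hour), tolerance = 1e-4)
})

test_that("two well-separated classes are recovered with correct curves", {
  curves <- rbind(c(180, -2, 0), c(120, 3, -0.15))
  cfg <- sim_config(n_patients = 500, seed = 34,
                    class_proportions = c(0.5, 0.5),
                    class_curves = curves,
                    random_intercept_sd = 5, residual_sd = 5)
  sim <- generate_cohort(cfg)
  f <- fit_lgmm(sim$glucose, K = 2, seed = 34, n_restarts = 3)
  expect_lt(abs(f$pi[1] - 0.5), 0.05)
  # match fitted classes to truth by intercept
  ord <- order(f$coefficients[1, ], decreasing = TRUE)
  for (j in 1:2) {
    k <- ord[j]
    for (r in 1:3) {
      expect_lt(abs(f$coefficients[r, k] - curves[j, r]),
                3 * f$coef_se[r, k] + 1e-8)
    }
  }
})

test_that("the near-noiseless limit classifies almost every patient", {
  curves <- rbind(c(180, -2, 0), c(120, 3, -0.15))
  cfg <- sim_config(n_patients = 300, seed = 35,
                    class_proportions = c(0.5, 0.5), class_curves = curves,
                    random_intercept_sd = 0, residual_sd = 0.1)
  sim <- generate_cohort(cfg)
  f <- fit_lgmm(sim$glucose, K = 2, seed = 35, n_restarts = 2)
  expect_gt(f$entropy, 0.99)
  asg <- assign_classes(f)
  # fitted labels are share-ordered; map to truth by majority vote
  tab <- table(sim$classes$class, asg$class)
  expect_gt(sum(apply(tab, 1, max)) / 300, 0.99)
})

test_that("MAP assignment breaks ties toward the lower class index", {
  fake <- structure(list(
    patient_ids = c("a", "b"),
    n_patients = 2L,
    map_class = max.col(rbind(c(0.5, 0.5), c(0.1, 0.9)),
                        ties.method = "first"),
    posteriors = rbind(c(0.5, 0.5), c(0.1, 0.9))
  ), class = "lgmm_fit")
  asg <- assign_classes(fake)
  expect_equal(asg$class, c(1L, 2L))
  expect_equal(asg$posterior, c(0.5, 0.9))
})

test_that("label permutation leaves fit statistics unchanged", {
  set.seed(36)
  W <- matrix(rgamma(40 * 3, 1), 40)
  W <- W / rowSums(W)
  expect_equal(compute_entropy(W), compute_entropy(W[, c(3, 1, 2)]))
  # fitted reports order classes by descending share
  cfg <- sim_config(n_patients = 400, seed = 36)
  sim <- generate_cohort(cfg)
  f <- fit_lgmm(sim$glucose, K = 3, seed = 36, n_restarts = 2)
  expect_true(all(diff(f$pi) <= 1e-12))
})

test_that("class selection filters on the four conditions and ranks by BIC", {
  fake <- function(K, ll, bic, aic, entropy, shares, post) {
    structure(list(K = K, loglik = ll, aic = aic, bic = bic,
                   entropy = entropy, class_shares = shares,
                   mean_posterior = post), class = "lgmm_fit")
  }
  # single passing candidate is selected
  sel1 <- select_classes(list(fake(2, -100, 250, 240, 0.9, c(0.6, 0.4),
                                   c(0.9, 0.9))))
  expect_equal(sel1$selected_K, 2)
  # argmin BIC among survivors
  ms <- list(
    fake(2, -100, 10000, 9990, 0.9, c(0.6, 0.4), c(0.9, 0.9)),
    fake(3, -95, 9950, 9940, 0.9, c(0.5, 0.3, 0.2), c(0.9, 0.9, 0.9)),
    fake(4, -90, 9990, 9980, 0.9, rep(0.25, 4), rep(0.9, 4))
  )
  expect_equal(select_classes(ms)$selected_K, 3)
  # entropy, share and posterior gates
  ms2 <- list(
    fake(2, -100, 9000, 8990, 0.5, c(0.6, 0.4), c(0.9, 0.9)),
    fake(3, -95, 9100, 9090, 0.9, c(0.99, 0.005, 0.005), c(0.9, 0.9, 0.9)),
    fake(4, -90, 9200, 9190, 0.9, rep(0.25, 4), c(0.9, 0.9, 0.9, 0.6))
  )
  sel2 <- select_classes(ms2)
  expect_true(is.na(sel2$selected_K))
  expect_equal(sel2$table$pass_all, c(FALSE, FALSE, FALSE))
})

test_that("fit errors are informative on degenerate input", {
  g <- data.frame(patient_id = rep(1:5, each = 2), time_h = rep(c(0, 4), 5),
                  glucose_mgdl = 100)
  expect_error(fit_lgmm(g, K = 2), "at least 3 readings")
  g6 <- glucose_long(matrix(rnorm(4 * 6, 140, 5), 4))
  expect_error(fit_lgmm(g6, K = 6), "more classes than patients")
})
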