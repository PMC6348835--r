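test_that("stratified folds deal each patient round-robin", {
  d20 <- toy_ema(20, patients = rep("A", 20))
  f <- stratified_folds(d20, k = 10, seed = 1)
  expect_equal(as.vector(table(f)), rep(2L, 10))  # 20 obs, k=10: 2 per fold

  # a patient with 3 observations lands in exactly 3 distinct folds
  d13 <- toy_ema(13, patients = c(rep("A", 10), rep("B", 3)))
  f13 <- stratified_folds(d13, k = 10, seed = 2)
  expect_equal(length(unique(f13[d13$patient_id == "B"])), 3)

  d3 <- toy_ema(3, patients = rep("B", 3))
  expect_error(stratified_folds(d3, k = 1), class = "ordema_argument_error")
  expect_error(stratified_folds(d3, k = 4), class = "ordema_argument_error")
})

test_that("folds partition the data with balanced per-patient counts", {
  set.seed(3)
  for (rep in 1:25) {
    J <- sample(2:6, 1)
    n_j <- sample(3:15, J, replace = TRUE)
    d <- toy_ema(sum(n_j), patients = rep(sprintf("P%02d", 1:J), n_j))
    k <- sample(2:6, 1)
    f <- stratified_folds(d, k)
    expect_equal(length(f), nrow(d))
    expect_true(all(f %in% 1:k))
    for (p in unique(d$patient_id)) {
      counts <- tabulate(f[d$patient_id == p], k)
      expect_lte(max(counts) - min(counts), 1)
      if (sum(counts) >= k) expect_true(all(counts >= 1))
    }
  }
})

test_that("fold assignment is invariant to record order under a fixed seed", {
  d <- small_cohort(71, J = 6, n_per = 9)$data
  perm <- withr::with_seed(4, sample(nrow(d)))
  f_orig <- stratified_folds(d, k = 3, seed = 5)
  f_perm <- stratified_folds(d[perm, ], k = 3, seed = 5)
  expect_identical(f_orig[perm], f_perm)
})

test_that("posterior predictive reduces exactly for one and two draws", {
  sim <- small_cohort(72, J = 3, n_per = 4)
  d <- sim$data
  fit <- fit_ordinal(d, model_spec("cumulative", heterogeneous = TRUE),
                     mcmc = tiny_mcmc(6))
  lay <- fit$layout

  fit1 <- fit
  fit1$theta <- fit$theta[1, , drop = FALSE]
  pp1 <- posterior_predictive(fit1, d)
  pieces <- ordema:::.constrain(lay, fit$theta[1, ], fit$patients)
  manual <- t(vapply(seq_len(nrow(d)), function(i) {
    olm_category_probs(as.numeric(d[i, ema_predictors]),
                       pieces$beta[d$patient_id[i], ], pieces$alpha)
  }, numeric(10)))
  expect_equal(pp1$prob, manual, tolerance = 1e-12)

  fit2 <- fit
  fit2$theta <- fit$theta[1:2, , drop = FALSE]
  pp2 <- posterior_predictive(fit2, d)
  p2 <- ordema:::.constrain(lay, fit$theta[2, ], fit$patients)
  manual2 <- t(vapply(seq_len(nrow(d)), function(i) {
    olm_category_probs(as.numeric(d[i, ema_predictors]),
                       p2$beta[d$patient_id[i], ], p2$alpha)
  }, numeric(10)))
  expect_equal(pp2$prob, (manual + manual2) / 2, tolerance = 1e-12)
  expect_equal(rowSums(pp2$prob), rep(1, nrow(d)), tolerance = 1e-9)
})

test_that("patients unseen in training fall back to the population slopes", {
  sim <- small_cohort(73, J = 4, n_per = 6)
  train <- sim$data[sim$data$patient_id != "P004", ]
  test <- sim$data[sim$data$patient_id == "P004", ]
  fit <- fit_ordinal(train, model_spec("cumulative", heterogeneous = TRUE),
                     mcmc = tiny_mcmc(7))
  expect_message(pp <- posterior_predictive(fit, test), "unseen")
  expect_equal(rowSums(pp$prob), rep(1, nrow(test)), tolerance = 1e-9)
  # and equals the homogeneous prediction path evaluated at the delta draws
  S <- nrow(fit$theta)
  acc <- matrix(0, nrow(test), 10)
  for (s in seq_len(S)) {
    pcs <- ordema:::.constrain(fit$layout, fit$theta[s, ], fit$patients)
    for (i in seq_len(nrow(test))) {
      acc[i, ] <- acc[i, ] +
        olm_category_probs(as.numeric(test[i, ema_predictors]),
                           pcs$delta, pcs$alpha)
    }
  }
  expect_equal(pp$prob, acc / S, tolerance = 1e-10)
})

test_that("point prediction rules follow their stated conventions", {
  expect_equal(point_predictions(c(0.6, 0.3, 0.1), "median"), 1L)
  expect_equal(point_predictions(c(0.3, 0.3, 0.4), "median"), 2L)
  expect_equal(point_predictions(c(0.3, 0.3, 0.4), "mode"), 3L)
  expect_equal(point_predictions(c(0.5, 0.5, 0), "mode"), 1L)  # low tie-break
  P <- rbind(c(0.6, 0.3, 0.1), c(0.3, 0.3, 0.4))
  expect_equal(point_predictions(P, "median"), c(1L, 2L))
})

test_that("error metrics follow their definitions and Jensen's inequality", {
  expect_equal(error_metrics(1:5, 1:5), tibble::tibble(rmse = 0, mae = 0))
  m <- error_metrics(c(3, 5), c(2, 3))
  expect_equal(m$rmse, sqrt(2.5))
  expect_equal(m$mae, 1.5)
  expect_error(error_metrics(1:3, 1:2), class = "ordema_argument_error")
  set.seed(8)
  for (rep in 1:20) {
    o <- sample(1:10, 30, TRUE)
    p <- sample(1:10, 30, TRUE)
    mm <- error_metrics(o, p)
    expect_gte(mm$rmse, mm$mae)
  }
})

test_that("DIC matches its hand-computed definition", {
  r <- dic(c(10, 14), deviance_at_mean = 9)
  expect_equal(r$mean_deviance, 12)
  expect_equal(r$p_d, 3)
  expect_equal(r$dic, 15)
  # zero-variance draws: p_D = 0 and DIC equals the common deviance
  r0 <- dic(c(7, 7, 7), deviance_at_mean = 7)
  expect_equal(r0$p_d, 0)
  expect_equal(r0$dic, 7)
  expect_error(dic(c(1, NaN), deviance_at_mean = 1),
               class = "ordema_runtime_error")
})

test_that("WAIC matches its hand-computed definition", {
  # identical draws, per-record likelihood 1/2, N = 2
  ll <- matrix(log(0.5), nrow = 3, ncol = 2)
  r <- waic(ll)
  expect_equal(r$p_waic, 0)
  expect_equal(r$waic, 4 * log(2), tolerance = 1e-10)
  # 2 x 1 matrix against the closed form
  ll2 <- matrix(c(log(0.2), log(0.8)), 2, 1)
  lppd <- log(mean(c(0.2, 0.8)))
  p_waic <- var(c(log(0.2), log(0.8)))
  expect_equal(waic(ll2)$waic, -2 * (lppd - p_waic), tolerance = 1e-10)
  # uniformly better likelihoods decrease WAIC
  expect_lt(waic(ll + 0.5)$waic, waic(ll)$waic)
  expect_error(waic(matrix(c(1, -Inf), 1)), class = "ordema_runtime_error")
})

test_that("a single-draw fit has WAIC = DIC = its deviance", {
  sim <- small_cohort(74, J = 4, n_per = 6)
  fit <- fit_ordinal(sim$data, model_spec("cumulative"),
                     mcmc = mcmc_config(chains = 1, iterations = 400,
                                        post_warmup = 1, thin = 1, seed = 9))
  expect_equal(nrow(fit$theta), 1)
  dev <- -2 * sum(fit$loglik[1, ])
  expect_equal(waic(fit)$waic, dev, tolerance = 1e-9)
  expect_equal(dic(fit)$dic, dev, tolerance = 1e-9)
})

test_that("mean baselines use training means with a global fallback", {
  train <- toy_ema(3, patients = c("A", "A", "B"))
  train$self_esteem <- c(2, 2, 8)
  test <- toy_ema(3, patients = c("A", "B", "C"))
  expect_warning(b <- mean_baselines(train, test), "global mean")
  expect_equal(b$mean_model, rep(4, 3))  # mean of (2, 2, 8)
  expect_equal(b$mean_individual, c(2, 8, 4))
  expect_error(mean_baselines(train[0, ], test),
               class = "ordema_argument_error")
  # two-point example: global mean is the arithmetic mean of the outcomes
  tr <- toy_ema(2, patients = c("A", "B"))
  tr$self_esteem <- c(2, 4)
  expect_equal(unique(mean_baselines(tr, tr)$mean_model), 3)
})

test_that("the signed-rank comparison matches exact and reference results", {
  expect_equal(compare_errors_wilcoxon(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  # six unit differences: exact two-sided p = 2/2^6
  r <- compare_errors_wilcoxon(c(2, 2, 2, 2, 2, 2), c(1, 1, 1, 1, 1, 1))
  expect_equal(r$p_value, 0.03125, tolerance = 1e-12)
  # swapping the inputs keeps p, complements the rank-sum statistic
  r2 <- compare_errors_wilcoxon(c(1, 1, 1, 1, 1, 1), c(2, 2, 2, 2, 2, 2))
  expect_equal(r2$p_value, r$p_value)
  expect_equal(r$statistic + r2$statistic, 6 * 7 / 2)
  # tie-free exact case agrees with the standard implementation
  set.seed(10)
  a <- c(0.3, 1.2, 2.7, 0.1, 4.4, 2.2, 0.9, 3.3)
  b <- c(0.5, 0.4, 1.1, 0.9, 1.2, 3.1, 0.2, 0.6)
  ref <- stats::wilcox.test(a, b, paired = TRUE, exact = TRUE)
  expect_equal(compare_errors_wilcoxon(a, b)$p_value, ref$p.value,
               tolerance = 1e-12)
  # large-sample path agrees with the corrected normal approximation
  a2 <- runif(80)
  b2 <- runif(80)
  ref2 <- suppressWarnings(
    stats::wilcox.test(a2, b2, paired = TRUE, exact = FALSE, correct = TRUE))
  expect_equal(compare_errors_wilcoxon(a2, b2)$p_value, ref2$p.value,
               tolerance = 1e-10)
  expect_error(compare_errors_wilcoxon(1:3, 1:4),
               class = "ordema_argument_error")
})

test_that("cross-validation pools every record exactly once and reports all rows", {
  sim <- small_cohort(75, J = 8, n_per = 8)
  cv <- cross_validate(sim$data, model_spec("cumulative", heterogeneous = TRUE),
                       k = 3, mcmc = tiny_mcmc(11), fold_seed = 12)
  expect_equal(sort(cv$predictions$row), seq_len(nrow(sim$data)))
  expect_equal(cv$predictions$observed, as.integer(sim$data$self_esteem))
  expect_equal(cv$metrics$model[1], "cumulative_heterogeneous")
  expect_true(all(is.finite(cv$metrics$rmse)))
  expect_true(all(is.finite(cv$metrics$mae)))
  expect_true(all(is.finite(unlist(cv$metrics[1, c("dic", "waic")]))))
  expect_true(all(is.na(unlist(cv$metrics[2:3, c("dic", "waic")]))))
  expect_true(all(cv$metrics$rmse >= cv$metrics$mae))
  expect_equal(nrow(cv$wilcoxon), 3)  # all pairs of model and baselines
})
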