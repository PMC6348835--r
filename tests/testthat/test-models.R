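test_that("cumulative category probabilities match the logistic-CDF oracle", {
  # C = 2, linear predictor 0: both categories equally likely
  expect_equal(olm_category_probs(rep(0, 5), rep(0, 5), 0), c(0.5, 0.5))
  # C = 3 frozen oracle: plogis differencing at alpha = (-1, 1)
  p <- olm_category_probs(rep(0, 5), rep(0, 5), c(-1, 1))
  expect_equal(round(p, 4), c(0.2689, 0.4621, 0.2689))
  expect_equal(p, c(plogis(-1), plogis(1) - plogis(-1), 1 - plogis(1)),
               tolerance = 1e-12)
  expect_error(olm_category_probs(rep(1, 5), rep(0, 5), c(1, -1)),
               class = "ordema_argument_error")
})

test_that("stereotype category probabilities match the softmax oracle", {
  C <- 3
  # zero linear predictor and zero intercepts: uniform
  expect_equal(
    stereotype_category_probs(rep(0, 5), rep(0, 5), c(0, 0, 0), c(0, 0.5, 1)),
    rep(1 / 3, 3))
  # frozen oracle: softmax of (0, 1, 2)
  x <- c(1, 0, 0, 0, 0)
  p <- stereotype_category_probs(x, c(1, 0, 0, 0, 0), c(0, 0.5, 1),
                                 c(0, 0.5, 1))
  expect_equal(round(p, 4), c(0.0900, 0.2447, 0.6652))
  expect_equal(p, exp(0:2) / sum(exp(0:2)), tolerance = 1e-12)
  # score constraint violations are rejected
  expect_error(
    stereotype_category_probs(x, rep(0, 5), c(0, 0, 0), c(0, 0.2, 0.9)),
    class = "ordema_argument_error")
  expect_error(
    stereotype_category_probs(x, rep(0, 5), c(0.5, 0, 0), c(0, 0.5, 1)),
    class = "ordema_argument_error")
})

test_that("phi_from_gamma builds monotone scores with fixed endpoints", {
  expect_equal(phi_from_gamma(rep(1 / 3, 3)), c(0, 1 / 3, 2 / 3, 1))
  expect_equal(phi_from_gamma(c(1, 0, 0)), c(0, 1, 1, 1))
  expect_error(phi_from_gamma(c(0.5, 0.2)), class = "ordema_argument_error")
  expect_error(phi_from_gamma(c(-0.1, 1.1)), class = "ordema_argument_error")
  set.seed(11)
  for (C in 2:10) {
    g <- rgamma(C - 1, 0.7)
    g <- g / sum(g)
    phi <- phi_from_gamma(g)
    expect_equal(phi[1], 0)
    expect_equal(phi[C], 1)
    expect_false(is.unsorted(phi))
  }
})

test_that("both probability operations return simplexes for random inputs", {
  set.seed(21)
  for (C in 2:10) {
    for (rep in 1:20) {
      x <- sample(1:10, 5, replace = TRUE)
      cp <- random_cumulative_pars(C)
      p1 <- olm_category_probs(x, cp$slopes, cp$cutpoints)
      expect_equal(sum(p1), 1, tolerance = 1e-12)
      expect_true(all(p1 >= 0 & p1 <= 1))
      sp <- random_stereotype_pars(C)
      p2 <- stereotype_category_probs(x, sp$slopes, sp$intercepts, sp$scores)
      expect_equal(sum(p2), 1, tolerance = 1e-12)
      expect_true(all(p2 >= 0 & p2 <= 1))
    }
  }
})

test_that("cumulative model is stochastically ordered in the linear predictor", {
  set.seed(22)
  cutpoints <- sort(rnorm(9, 0, 3))
  slopes <- c(1, 0, 0, 0, 0)
  etas <- c(-3, -1, 0, 1, 3)
  cums <- sapply(etas, function(e) {
    cumsum(olm_category_probs(c(e, 0, 0, 0, 0), slopes, cutpoints))[1:9]
  })
  # every cumulative probability P(Y <= c) strictly decreases with eta
  for (c_idx in 1:9) expect_true(all(diff(cums[c_idx, ]) < 0))
})

test_that("stereotype model with zero intercepts shifts mass upward in eta", {
  set.seed(23)
  g <- rgamma(9, 1)
  phi <- phi_from_gamma(g / sum(g))
  slopes <- c(1, 0, 0, 0, 0)
  expected_cat <- sapply(seq(-4, 4, by = 1), function(e) {
    sum(seq_len(10) *
          stereotype_category_probs(c(e, 0, 0, 0, 0), slopes, rep(0, 10), phi))
  })
  expect_false(is.unsorted(expected_cat))
})

test_that("probabilities and log-likelihoods stay finite at extreme |x'b|", {
  cutpoints <- sort(rnorm(9))
  for (eta in c(-1e4, 1e4)) {
    x <- c(eta, 0, 0, 0, 0)
    s <- c(1, 0, 0, 0, 0)
    p1 <- olm_category_probs(x, s, cutpoints)
    expect_false(any(is.nan(p1)))
    expect_equal(sum(p1), 1, tolerance = 1e-12)
    p2 <- stereotype_category_probs(x, s, c(0, rnorm(9)),
                                    phi_from_gamma(rep(1 / 9, 9)))
    expect_false(any(is.nan(p2)))
    expect_equal(sum(p2), 1, tolerance = 1e-9)
  }
  # pointwise log-likelihood remains finite (floored, never NaN/-Inf)
  d <- toy_ema(4)
  ps <- parameter_set("cumulative", delta = c(1e3, 0, 0, 0, 0),
                      alpha = sort(rnorm(9)))
  ll <- pointwise_log_lik(model_spec("cumulative"), ps, d)
  expect_true(all(is.finite(ll)))
})

test_that("pointwise log-likelihood equals the per-record brute force", {
  set.seed(31)
  d <- small_cohort(31, J = 5, n_per = 6)$data
  J <- 5
  beta <- matrix(rnorm(J * 5, 0, 0.4), J, 5,
                 dimnames = list(unique(d$patient_id), NULL))
  delta <- rnorm(5, 0, 0.4)

  # cumulative, heterogeneous
  alpha <- sort(rnorm(9, 27, 6))
  ps <- parameter_set("cumulative", delta = delta, alpha = alpha, beta = beta)
  ll <- pointwise_log_lik(model_spec("cumulative", heterogeneous = TRUE),
                          ps, d)
  brute <- vapply(seq_len(nrow(d)), function(i) {
    x <- as.numeric(d[i, ema_predictors])
    p <- olm_category_probs(x, beta[d$patient_id[i], ], alpha)
    log(p[d$self_esteem[i]])
  }, numeric(1))
  expect_equal(ll, brute, tolerance = 1e-12)

  # stereotype, heterogeneous
  g <- rgamma(9, 1)
  g <- g / sum(g)
  ps2 <- parameter_set("stereotype", delta = delta,
                       alpha = c(0, rnorm(9)), beta = beta, gamma = g)
  ll2 <- pointwise_log_lik(model_spec("stereotype", heterogeneous = TRUE),
                           ps2, d)
  brute2 <- vapply(seq_len(nrow(d)), function(i) {
    x <- as.numeric(d[i, ema_predictors])
    p <- stereotype_category_probs(x, beta[d$patient_id[i], ], ps2$alpha,
                                   ps2$phi)
    log(p[d$self_esteem[i]])
  }, numeric(1))
  expect_equal(ll2, brute2, tolerance = 1e-12)

  # homogeneous spec with beta rows all equal to delta reduces exactly
  beta_eq <- matrix(rep(delta, each = J), J, 5,
                    dimnames = list(unique(d$patient_id), NULL))
  ps_hom <- parameter_set("cumulative", delta = delta, alpha = alpha)
  ps_het <- parameter_set("cumulative", delta = delta, alpha = alpha,
                          beta = beta_eq)
  expect_identical(
    pointwise_log_lik(model_spec("cumulative"), ps_hom, d),
    pointwise_log_lik(model_spec("cumulative", heterogeneous = TRUE),
                      ps_het, d))
})

test_that("log prior density matches a componentwise closed-form oracle", {
  set.seed(41)
  prior <- prior_config()
  sigma <- sqrt(prior$variance)
  for (rep in 1:5) {
    C <- sample(3:10, 1)
    J <- 4
    delta <- rnorm(5)
    beta <- matrix(rnorm(J * 5), J, 5)
    alpha_c <- sort(rnorm(C - 1))
    spec_c <- model_spec("cumulative", heterogeneous = TRUE, n_categories = C)
    ps_c <- parameter_set("cumulative", delta, alpha_c, beta,
                          n_categories = C)
    oracle <- sum(dnorm(delta, prior$slope_means, sigma, log = TRUE)) +
      sum(dnorm(alpha_c, 0, sigma, log = TRUE)) +
      sum(vapply(seq_len(J), function(j)
        sum(dnorm(beta[j, ], delta, sigma, log = TRUE)), numeric(1)))
    expect_equal(log_prior_density(spec_c, prior, ps_c), oracle,
                 tolerance = 1e-10)

    g <- rgamma(C - 1, 1)
    g <- g / sum(g)
    spec_s <- model_spec("stereotype", n_categories = C)
    ps_s <- parameter_set("stereotype", delta, c(0, rnorm(C - 1)),
                          gamma = g, n_categories = C)
    oracle_s <- sum(dnorm(delta, prior$slope_means, sigma, log = TRUE)) +
      sum(dnorm(ps_s$alpha[-1], 0, sigma, log = TRUE)) +
      lgamma(C - 1)  # symmetric Dirichlet(1) normalizer
    expect_equal(log_prior_density(spec_s, prior, ps_s), oracle_s,
                 tolerance = 1e-10)
  }
})

test_that("symmetric Dirichlet(1) contributes log Gamma(C-1) for C = 4", {
  prior <- prior_config()
  spec <- model_spec("stereotype", n_categories = 4)
  base <- sum(dnorm(prior$slope_means * 0, prior$slope_means, 10,
                    log = TRUE)) + sum(dnorm(c(0.3, -0.2, 1), 0, 10,
                                             log = TRUE))
  for (g in list(c(0.2, 0.3, 0.5), c(1, 1, 1) / 3, c(0.6, 0.05, 0.35))) {
    ps <- parameter_set("stereotype", delta = rep(0, 5),
                        alpha = c(0, 0.3, -0.2, 1), gamma = g,
                        n_categories = 4)
    expect_equal(log_prior_density(spec, prior, ps) - base, log(2),
                 tolerance = 1e-10)
  }
})

test_that("constraint violations have zero prior support", {
  prior <- prior_config()
  spec <- model_spec("cumulative", n_categories = 4)
  bad <- list(family = "cumulative", n_categories = 4L,
              delta = setNames(rep(0, 5), ema_predictors),
              alpha = c(1, -1, 0), beta = NULL, gamma = NULL, phi = NULL)
  class(bad) <- "parameter_set"
  expect_message(lp <- log_prior_density(spec, prior, bad))
  expect_identical(lp, -Inf)
})

test_that("parameter sets survive a JSON round trip", {
  set.seed(51)
  g <- rgamma(9, 1)
  g <- g / sum(g)
  beta <- matrix(rnorm(15), 3, 5, dimnames = list(c("A", "B", "C"), NULL))
  ps <- parameter_set("stereotype", delta = rnorm(5),
                      alpha = c(0, rnorm(9)), beta = beta, gamma = g)
  path <- withr::local_tempfile(fileext = ".json")
  write_parameter_set(ps, path)
  ps2 <- read_parameter_set(path)
  expect_equal(ps2$delta, ps$delta)
  expect_equal(ps2$alpha, ps$alpha)
  expect_equal(ps2$gamma, ps$gamma)
  expect_equal(ps2$phi, ps$phi)
  expect_equal(ps2$beta, ps$beta)
})
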