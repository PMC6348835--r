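#' Patient-stratified fold assignment
#'
#' Within each patient the observations are shuffled and dealt
#' round-robin across the `k` folds (with a random starting fold), so
#' per-patient counts differ by at most one across folds and every
#' patient with at least `k` observations appears in every fold. Folds
#' therefore partition the dataset while keeping every patient in both
#' training and test sets.
#'
#' @param data A diary tibble.
#' @param k Number of folds (>= 2).
#' @param seed Optional integer seed.
#' @return Integer vector of fold labels in `1..k`, one per record.
#' @export
stratified_folds <- function(data, k, seed = NULL) {
  k <- as.integer(k)
  if (k < 2) abort("`k` must be >= 2", class = "ordema_argument_error")
  if (k > nrow(data)) {
    abort("`k` cannot exceed the number of records",
          class = "ordema_argument_error")
  }
  assign_folds <- function() {
    folds <- integer(nrow(data))
    for (idx in split(seq_len(nrow(data)), data$patient_id)) {
      idx <- idx[order(data$time_index[idx])]  # canonical within-patient order
      n_j <- length(idx)
      perm <- sample(n_j)
      start <- sample.int(k, 1)
      folds[idx[perm]] <- ((start - 1 + seq_len(n_j) - 1) %% k) + 1L
    }
    folds
  }
  if (!is.null(seed)) withr::with_seed(seed, assign_folds()) else assign_folds()
}

#' Posterior predictive distribution for test records
#'
#' Per test record, the category probabilities are averaged over all
#' stored posterior draws, using the record's patient slope draws for
#' heterogeneous models and the population slope draws otherwise.
#' Patients unseen in training fall back to the population slopes (with
#' a message), which is the natural prediction for a new patient.
#'
#' @param fit An [fit_ordinal()] result.
#' @param newdata A complete diary tibble of test records.
#' @param rule Point-prediction rule, `"median"` or `"mode"`; see
#'   [point_predictions()].
#' @return An object of class `ordema_pred`: list with `prob` (N x C
#'   matrix of draw-averaged simplexes), `point` (integer predictions),
#'   `observed` (if present in `newdata`), `patient_id`.
#' @export
posterior_predictive <- function(fit, newdata, rule = c("median", "mode")) {
  rule <- match.arg(rule)
  if (fit$prior_only) {
    abort("cannot predict from a prior-only fit",
          class = "ordema_argument_error")
  }
  spec <- fit$spec
  mf <- .model_frame(newdata, spec$n_categories)
  lay <- fit$layout
  theta <- fit$theta
  S <- nrow(theta)

  # map test patients onto training beta rows; NA = unseen
  row_of <- match(mf$patients, fit$patients)
  if (lay$het && anyNA(row_of)) {
    inform(paste0("posterior_predictive: ",
                  sum(is.na(row_of[mf$pid])),
                  " record(s) from patients unseen in training use the ",
                  "population slopes"))
  }
  acc <- matrix(0, mf$N, mf$C)
  for (s in seq_len(S)) {
    pieces <- .constrain(lay, theta[s, ], fit$patients)
    eta <- if (lay$het) {
      B <- rbind(pieces$beta,
                 matrix(pieces$delta, 1, lay$K))  # fallback row
      ridx <- row_of[mf$pid]
      ridx[is.na(ridx)] <- nrow(B)
      rowSums(mf$X * B[ridx, , drop = FALSE])
    } else {
      as.numeric(mf$X %*% pieces$delta)
    }
    acc <- acc + .prob_matrix(spec$family, eta, pieces$alpha, pieces$phi)
  }
  prob <- acc / S
  structure(
    list(prob = prob, point = point_predictions(prob, rule),
         observed = if ("self_esteem" %in% names(newdata))
           as.integer(newdata$self_esteem),
         patient_id = newdata$patient_id, rule = rule),
    class = "ordema_pred"
  )
}

#' @export
print.ordema_pred <- function(x, ...) {
  cat(sprintf("<ordema_pred> %d records, C = %d, %s-rule point predictions\n",
              nrow(x$prob), ncol(x$prob), x$rule))
  invisible(x)
}

#' @export
as_tibble.ordema_pred <- function(x, ...) {
  out <- tibble::tibble(patient_id = x$patient_id, predicted = x$point)
  if (!is.null(x$observed)) out$observed <- x$observed
  probs <- tibble::as_tibble(x$prob, .name_repair = function(nms)
    paste0(".prob_", seq_along(nms)))
  dplyr::bind_cols(out, probs)
}

#' Point predictions from predictive simplexes
#'
#' `"median"` returns the smallest category whose cumulative predictive
#' probability reaches 0.5 (the optimal point prediction under absolute
#' error for an ordinal outcome); `"mode"` returns the most probable
#' category, ties broken toward the lower category.
#'
#' @param x An `ordema_pred`, a probability matrix (rows are records)
#'   or a single probability vector.
#' @param rule `"median"` or `"mode"`.
#' @return Integer vector of predicted categories.
#' @export
point_predictions <- function(x, rule = c("median", "mode")) {
  rule <- match.arg(rule)
  if (inherits(x, "ordema_pred")) x <- x$prob
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  if (rule == "median") {
    cp <- t(apply(x, 1, cumsum))
    if (ncol(x) == 1) cp <- matrix(cp, ncol = 1)
    as.integer(apply(cp >= 0.5 - 1e-12, 1, which.max))
  } else {
    as.integer(apply(x, 1, which.max))
  }
}

#' Prediction error metrics
#'
#' @param observed,predicted Equal-length numeric vectors.
#' @return A one-row tibble with `rmse` and `mae`.
#' @export
error_metrics <- function(observed, predicted) {
  if (length(observed) != length(predicted) || length(observed) == 0) {
    abort("`observed` and `predicted` must have equal positive length",
          class = "ordema_argument_error")
  }
  e <- observed - predicted
  tibble::tibble(rmse = sqrt(mean(e^2)), mae = mean(abs(e)))
}

#' Deviance information criterion
#'
#' `DIC = mean(D) + p_D` with deviance draws `D = -2 * loglik` and
#' effective parameter count `p_D = mean(D) - D(posterior mean)`. For a
#' fitted model the posterior mean is taken on the sampler's
#' unconstrained scale and transformed back, so the plugged-in
#' parameters always satisfy the model constraints.
#'
#' @param x An `ordema_fit`, or a numeric vector of deviance draws.
#' @param ... Passed to methods.
#' @return A list with `dic`, `p_d`, `mean_deviance`,
#'   `deviance_at_mean`.
#' @export
dic <- function(x, ...) UseMethod("dic")

#' @rdname dic
#' @param deviance_at_mean Deviance evaluated at the posterior mean of
#'   the parameters (numeric-vector method).
#' @export
dic.numeric <- function(x, deviance_at_mean, ...) {
  if (!all(is.finite(x)) || !is.finite(deviance_at_mean)) {
    abort("non-finite deviance", class = "ordema_runtime_error")
  }
  mean_dev <- mean(x)
  p_d <- mean_dev - deviance_at_mean
  list(dic = mean_dev + p_d, p_d = p_d, mean_deviance = mean_dev,
       deviance_at_mean = deviance_at_mean)
}

#' @rdname dic
#' @export
dic.ordema_fit <- function(x, ...) {
  if (is.null(x$loglik)) {
    abort("fit has no stored log-likelihood (prior-only?)",
          class = "ordema_argument_error")
  }
  dev <- -2 * rowSums(x$loglik)
  theta_bar <- colMeans(x$theta)
  mf <- .model_frame(x$data, x$spec$n_categories)
  pieces <- .constrain(x$layout, theta_bar, x$patients)
  eta <- if (x$layout$het) {
    rowSums(mf$X * pieces$beta[mf$pid, , drop = FALSE])
  } else {
    as.numeric(mf$X %*% pieces$delta)
  }
  ll_bar <- if (x$spec$family == "cumulative") {
    .cum_loglik(mf$y, eta, pieces$alpha)
  } else {
    .ste_loglik(mf$y, eta, pieces$alpha, pieces$phi)
  }
  dic(dev, deviance_at_mean = -2 * sum(ll_bar))
}

#' Widely applicable information criterion
#'
#' `WAIC = -2 (lppd - p_waic)` with the log pointwise predictive
#' density computed stably through log-sum-exp and the penalty equal to
#' the summed per-observation posterior variances of the log-likelihood.
#'
#' @param x An `ordema_fit`, or a draws x observations matrix of
#'   pointwise log-likelihood values.
#' @param ... Passed to methods.
#' @return A list with `waic`, `lppd`, `p_waic`, `elpd`.
#' @export
waic <- function(x, ...) UseMethod("waic")

#' @rdname waic
#' @export
waic.matrix <- function(x, ...) {
  if (!all(is.finite(x))) {
    abort("non-finite log-likelihood entries", class = "ordema_runtime_error")
  }
  S <- nrow(x)
  lppd <- sum(apply(x, 2, logsumexp) - log(S))
  p_waic <- if (S > 1) sum(apply(x, 2, var)) else 0
  elpd <- lppd - p_waic
  list(waic = -2 * elpd, lppd = lppd, p_waic = p_waic, elpd = elpd)
}

#' @rdname waic
#' @export
waic.ordema_fit <- function(x, ...) {
  if (is.null(x$loglik)) {
    abort("fit has no stored log-likelihood (prior-only?)",
          class = "ordema_argument_error")
  }
  waic(x$loglik)
}

#' Mean-model baseline predictions
#'
#' The *mean model* predicts every test outcome with the arithmetic
#' mean of the training outcomes; the *mean individual model* predicts
#' with the patient's own training mean. Means are kept real-valued.
#' Test patients absent from training fall back to the global mean
#' (with a warning).
#'
#' @param train,test Diary tibbles.
#' @return A tibble with one row per test record: `patient_id`,
#'   `mean_model`, `mean_individual`.
#' @export
mean_baselines <- function(train, test) {
  if (nrow(train) == 0) {
    abort("`train` is empty", class = "ordema_argument_error")
  }
  global <- mean(train$self_esteem)
  by_patient <- tapply(train$self_esteem, train$patient_id, mean)
  indiv <- as.numeric(by_patient[test$patient_id])
  if (anyNA(indiv)) {
    warn(paste0("mean_baselines: ", sum(is.na(indiv)),
                " test record(s) from patients absent in training use the ",
                "global mean"))
    indiv[is.na(indiv)] <- global
  }
  tibble::tibble(patient_id = test$patient_id,
                 mean_model = global, mean_individual = indiv)
}

#' Paired Wilcoxon signed-rank test on absolute errors
#'
#' Two-sided signed-rank test for paired error vectors. Zero
#' differences are dropped; if all differences are zero the p-value is
#' 1 by convention. For 16 or fewer nonzero differences the exact
#' permutation distribution of the rank sum (ties handled by average
#' ranks) is enumerated; larger samples use the normal approximation
#' with tie correction and continuity correction.
#'
#' @param abs_errors_a,abs_errors_b Equal-length numeric vectors,
#'   paired by test record.
#' @return A one-row tibble with `statistic` (rank sum of positive
#'   differences), `p_value` and `n_nonzero`.
#' @export
compare_errors_wilcoxon <- function(abs_errors_a, abs_errors_b) {
  if (length(abs_errors_a) != length(abs_errors_b)) {
    abort("error vectors must have equal length",
          class = "ordema_argument_error")
  }
  d <- abs_errors_a - abs_errors_b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    return(tibble::tibble(statistic = 0, p_value = 1, n_nonzero = 0L))
  }
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  if (n <= 16) {
    # exact permutation distribution over the 2^n sign assignments,
    # via convolution on doubled (hence integer) ranks
    r2 <- as.integer(round(2 * r))
    tot <- sum(r2)
    f <- numeric(tot + 1)
    f[1] <- 1
    for (ri in r2) {
      g <- numeric(tot + 1)
      g[seq_len(tot + 1 - ri) + ri] <- f[seq_len(tot + 1 - ri)]
      f <- f + g
    }
    f <- f / 2^n
    v2 <- as.integer(round(2 * v))
    p_low <- sum(f[seq_len(v2 + 1)])
    p_high <- sum(f[(v2 + 1):(tot + 1)])
    p <- min(1, 2 * min(p_low, p_high))
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (v - mu - 0.5 * sign(v - mu)) / sqrt(sig2)
    p <- 2 * pnorm(-abs(z))
  }
  tibble::tibble(statistic = v, p_value = p, n_nonzero = as.integer(n))
}

#' Patient-stratified cross-validated evaluation of one model
#'
#' Fits the model on `k - 1` folds and predicts the held-out fold,
#' repeating over all folds so every record is predicted exactly once;
#' RMSE and MAE are computed on the pooled predictions. DIC and WAIC
#' come from one additional fit on the full dataset. Both mean-model
#' baselines are computed per fold on the same splits, and pairwise
#' Wilcoxon tests compare the absolute error vectors.
#'
#' @param data A complete diary tibble.
#' @param spec A [model_spec()].
#' @param prior A [prior_config()].
#' @param k Number of folds (default 10).
#' @param mcmc An [mcmc_config()].
#' @param fold_seed Optional integer seed for the fold assignment
#'   (independent of the MCMC seed).
#' @param rule Point-prediction rule (default `"median"`).
#' @return An object of class `ordema_cv`: `predictions` (pooled
#'   tibble), `metrics` (model and baseline rows), `wilcoxon`
#'   (pairwise tests), `fit_full` (full-data fit), `folds`.
#' @export
cross_validate <- function(data, spec, prior = prior_config(), k = 10,
                           mcmc = desk_profile(), fold_seed = NULL,
                           rule = c("median", "mode")) {
  rule <- match.arg(rule)
  data <- validate_ema(data, n_categories = spec$n_categories)
  folds <- stratified_folds(data, k, seed = fold_seed)
  preds <- vector("list", k)
  for (f in seq_len(k)) {
    train <- data[folds != f, , drop = FALSE]
    test <- data[folds == f, , drop = FALSE]
    mcmc_f <- mcmc
    if (!is.null(mcmc$seed)) mcmc_f$seed <- mcmc$seed + 100 * f
    fit_f <- fit_ordinal(train, spec, prior, mcmc_f)
    pp <- posterior_predictive(fit_f, test, rule = rule)
    base <- mean_baselines(train, test)
    preds[[f]] <- tibble::tibble(
      row = which(folds == f),
      patient_id = test$patient_id,
      time_index = test$time_index,
      fold = f,
      observed = as.integer(test$self_esteem),
      predicted = pp$point,
      mean_model = base$mean_model,
      mean_individual = base$mean_individual
    )
  }
  predictions <- dplyr::arrange(dplyr::bind_rows(preds), .data$row)
  mcmc_full <- mcmc
  if (!is.null(mcmc$seed)) mcmc_full$seed <- mcmc$seed + 1
  fit_full <- fit_ordinal(data, spec, prior, mcmc_full)
  ic_dic <- dic(fit_full)
  ic_waic <- waic(fit_full)

  model_label <- paste0(spec$family,
                        if (spec$heterogeneous) "_heterogeneous" else "")
  metr <- dplyr::bind_rows(
    dplyr::mutate(
      error_metrics(predictions$observed, predictions$predicted),
      model = model_label, dic = ic_dic$dic, waic = ic_waic$waic,
      .before = 1),
    dplyr::mutate(
      error_metrics(predictions$observed, predictions$mean_model),
      model = "mean_model", dic = NA_real_, waic = NA_real_, .before = 1),
    dplyr::mutate(
      error_metrics(predictions$observed, predictions$mean_individual),
      model = "mean_individual_model", dic = NA_real_, waic = NA_real_,
      .before = 1)
  )
  metr <- metr[, c("model", "rmse", "mae", "dic", "waic")]

  errs <- list(
    model = abs(predictions$observed - predictions$predicted),
    mean_model = abs(predictions$observed - predictions$mean_model),
    mean_individual_model = abs(predictions$observed -
                                  predictions$mean_individual)
  )
  names(errs)[1] <- model_label
  pairs <- utils::combn(names(errs), 2, simplify = FALSE)
  wil <- dplyr::bind_rows(lapply(pairs, function(pr) {
    dplyr::mutate(compare_errors_wilcoxon(errs[[pr[1]]], errs[[pr[2]]]),
                  model_a = pr[1], model_b = pr[2], .before = 1)
  }))

  structure(
    list(model = model_label, spec = spec, k = k, rule = rule,
         fold_seed = fold_seed, mcmc_seed = mcmc$seed,
         predictions = predictions, metrics = metr, wilcoxon = wil,
         fit_full = fit_full, folds = folds),
    class = "ordema_cv"
  )
}

#' @export
print.ordema_cv <- function(x, ...) {
  cat(sprintf("<ordema_cv> %s, %d-fold patient-stratified CV\n",
              x$model, x$k))
  print(x$metrics)
  invisible(x)
}
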