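#' Design of a synthetic EMA cohort
#'
#' Describes the layout of a simulated diary study: number of patients,
#' observations per patient, number of ordinal categories and the
#' marginal score distribution of each predictor item. The defaults
#' emulate the reference study design: 130 patients contributing 2326
#' complete observations (116 patients with 18 diary days and 14 with
#' 17), six items on a 1-10 scale, predictors uniform over the scale.
#'
#' @param n_patients Number of patients `J`.
#' @param obs_per_patient Integer scalar or length-`J` vector of diary
#'   days per patient. The default allocates `round(J * 2326/130)` total
#'   observations as evenly as possible.
#' @param n_categories Number of ordinal categories `C`.
#' @param predictor_marginals Optional `5 x C` matrix (rows in
#'   [ema_predictors] order) of per-item score probabilities; default
#'   uniform.
#' @param seed Optional integer seed stored with the design and used as
#'   the default by the generator functions.
#' @return An object of class `cohort_design`.
#' @export
cohort_design <- function(n_patients = 130, obs_per_patient = NULL,
                          n_categories = 10, predictor_marginals = NULL,
                          seed = NULL) {
  J <- as.integer(n_patients)
  if (is.na(J) || J < 1) {
    abort("`n_patients` must be a positive integer",
          class = "ordema_argument_error")
  }
  C <- as.integer(n_categories)
  if (C < 2) {
    abort("`n_categories` must be at least 2", class = "ordema_argument_error")
  }
  if (is.null(obs_per_patient)) {
    total <- round(J * 2326 / 130)
    base <- total %/% J
    extra <- total - base * J
    obs_per_patient <- c(rep(base + 1L, extra), rep(base, J - extra))
  } else if (length(obs_per_patient) == 1) {
    obs_per_patient <- rep(as.integer(obs_per_patient), J)
  }
  obs_per_patient <- as.integer(obs_per_patient)
  if (length(obs_per_patient) != J || any(obs_per_patient < 1)) {
    abort("`obs_per_patient` must be a positive integer scalar or length-J vector",
          class = "ordema_argument_error")
  }
  K <- length(ema_predictors)
  if (is.null(predictor_marginals)) {
    predictor_marginals <- matrix(1 / C, K, C,
                                  dimnames = list(ema_predictors, NULL))
  } else {
    predictor_marginals <- as.matrix(predictor_marginals)
    if (!all(dim(predictor_marginals) == c(K, C)) ||
        any(predictor_marginals < 0) ||
        any(abs(rowSums(predictor_marginals) - 1) > 1e-9)) {
      abort("`predictor_marginals` must be a 5 x C matrix of simplex rows",
            class = "ordema_argument_error")
    }
    rownames(predictor_marginals) <- ema_predictors
  }
  structure(
    list(n_patients = J, obs_per_patient = obs_per_patient,
         n_categories = C, predictor_marginals = predictor_marginals,
         seed = seed),
    class = "cohort_design"
  )
}

#' @export
print.cohort_design <- function(x, ...) {
  cat(sprintf("<cohort_design> J = %d patients, N = %d observations, C = %d\n",
              x$n_patients, sum(x$obs_per_patient), x$n_categories))
  invisible(x)
}

# moments of the linear predictor under the design's marginals, used to
# center the generated cutpoints/intercepts
.lp_moments <- function(design, slope_means, heterogeneity_sd) {
  C <- design$n_categories
  sc <- seq_len(C)
  mx <- as.numeric(design$predictor_marginals %*% sc)
  vx <- as.numeric(design$predictor_marginals %*% sc^2) - mx^2
  m <- sum(mx * slope_means)
  v <- sum(vx * (slope_means^2 + heterogeneity_sd^2) +
             mx^2 * heterogeneity_sd^2)
  list(mean = m, sd = sqrt(max(v, 1)))
}

#' Draw generating parameters for a synthetic cohort
#'
#' Patient slope rows are drawn as normal(`slope_means`,
#' `heterogeneity_sd^2`). Cumulative cutpoints are drawn from a normal
#' centered on the design's expected linear predictor (with its spread)
#' and then sorted, so the outcome occupies the whole scale. Stereotype
#' scores are built from a symmetric Dirichlet draw via
#' [phi_from_gamma()]; stereotype intercepts are centered at
#' `-phi_c * E(x'b)` so no category degenerates.
#'
#' The default population slopes are `+1` for mood, `-1` for worry and
#' `+0.5` for the remaining items, echoing the direction (and order of
#' magnitude) of the weakly informative prior means; the default
#' per-slope heterogeneity SD is 1.
#'
#' @param design A [cohort_design()].
#' @param family `"cumulative"` or `"stereotype"`.
#' @param slope_means Population slope 5-vector.
#' @param heterogeneity_sd Nonnegative 5-vector (or scalar) of patient
#'   slope standard deviations; 0 makes every patient identical.
#' @param dirichlet_concentration Concentration of the symmetric
#'   Dirichlet generating the stereotype scores.
#' @param seed Optional integer seed (defaults to the design's).
#' @return A [parameter_set()] with additional class `true_parameters`
#'   and attribute `heterogeneity_sd`.
#' @export
draw_true_parameters <- function(design,
                                 family = c("cumulative", "stereotype"),
                                 slope_means = c(mood = 1, worry = -1,
                                                 sleep = 0.5,
                                                 enjoyed_activities = 0.5,
                                                 social_contact = 0.5),
                                 heterogeneity_sd = 1,
                                 dirichlet_concentration = 1,
                                 seed = design$seed) {
  family <- match.arg(family)
  K <- length(ema_predictors)
  if (length(heterogeneity_sd) == 1) heterogeneity_sd <- rep(heterogeneity_sd, K)
  if (length(slope_means) != K || length(heterogeneity_sd) != K) {
    abort("`slope_means` and `heterogeneity_sd` must have 5 components",
          class = "ordema_argument_error")
  }
  if (any(heterogeneity_sd < 0)) {
    abort("`heterogeneity_sd` must be nonnegative",
          class = "ordema_argument_error")
  }
  draw <- function() {
    J <- design$n_patients
    C <- design$n_categories
    beta <- matrix(rep(slope_means, each = J), J, K) +
      matrix(rnorm(J * K), J, K) * rep(heterogeneity_sd, each = J)
    dimnames(beta) <- list(sprintf("P%03d", seq_len(J)), ema_predictors)
    mom <- .lp_moments(design, slope_means, heterogeneity_sd)
    if (family == "cumulative") {
      alpha <- sort(rnorm(C - 1, mom$mean, mom$sd))
      gamma <- NULL
    } else {
      gamma <- rgamma(C - 1, shape = dirichlet_concentration)
      gamma <- gamma / sum(gamma)
      phi <- phi_from_gamma(gamma)
      alpha <- c(0, -phi[-1] * mom$mean + rnorm(C - 1))
    }
    out <- parameter_set(family, delta = slope_means, alpha = alpha,
                         beta = beta, gamma = gamma, n_categories = C)
    attr(out, "heterogeneity_sd") <- setNames(heterogeneity_sd, ema_predictors)
    class(out) <- c("true_parameters", class(out))
    out
  }
  if (!is.null(seed)) withr::with_seed(seed, draw()) else draw()
}

#' Simulate an EMA diary dataset
#'
#' Predictor scores are drawn independently from the design's marginal
#' distributions; the outcome of each record is drawn from the category
#' probabilities of the generating family evaluated at that patient's
#' slope row. The result is a complete dataset: it passes
#' [filter_complete()] unchanged.
#'
#' @param params A [draw_true_parameters()] result (or any
#'   [parameter_set()] with a `J x 5` `beta`).
#' @param design The [cohort_design()] the parameters were drawn for.
#' @param seed Optional integer seed (defaults to the design's seed,
#'   offset so the parameter draw and the dataset draw differ).
#' @return A diary tibble with the columns in [ema_columns].
#' @export
simulate_ema <- function(params, design,
                         seed = if (!is.null(design$seed)) design$seed + 1L) {
  J <- design$n_patients
  C <- design$n_categories
  if (params$n_categories != C) {
    abort("`params` and `design` disagree on the number of categories",
          class = "ordema_argument_error")
  }
  if (is.null(params$beta) || nrow(params$beta) != J) {
    abort("`params$beta` must have one row per design patient",
          class = "ordema_argument_error")
  }
  draw <- function() {
    n_j <- design$obs_per_patient
    N <- sum(n_j)
    pid <- rep(seq_len(J), n_j)
    X <- vapply(ema_predictors, function(item) {
      sample.int(C, N, replace = TRUE,
                 prob = design$predictor_marginals[item, ])
    }, numeric(N))
    eta <- rowSums(X * params$beta[pid, , drop = FALSE])
    P <- .prob_matrix(params$family, eta, params$alpha, params$phi)
    cp <- t(apply(P, 1, cumsum))
    u <- runif(N)
    y <- rowSums(u > cp) + 1L
    y <- pmin(y, C)
    tibble::tibble(
      patient_id = rownames(params$beta)[pid],
      time_index = unlist(lapply(n_j, seq_len)),
      mood = X[, 1], worry = X[, 2], sleep = X[, 3],
      enjoyed_activities = X[, 4], social_contact = X[, 5],
      self_esteem = as.numeric(y)
    )
  }
  if (!is.null(seed)) withr::with_seed(seed, draw()) else draw()
}

#' Simulate a full cohort: parameters plus dataset
#'
#' Convenience wrapper drawing generating parameters and a dataset in
#' one call.
#'
#' @inheritParams draw_true_parameters
#' @return A list with elements `data` (diary tibble), `params`
#'   (generating [parameter_set()]) and `design`.
#' @export
simulate_cohort <- function(design, family = c("cumulative", "stereotype"),
                            slope_means = c(mood = 1, worry = -1, sleep = 0.5,
                                            enjoyed_activities = 0.5,
                                            social_contact = 0.5),
                            heterogeneity_sd = 1,
                            dirichlet_concentration = 1,
                            seed = design$seed) {
  family <- match.arg(family)
  params <- draw_true_parameters(design, family, slope_means,
                                 heterogeneity_sd, dirichlet_concentration,
                                 seed = seed)
  data <- simulate_ema(params, design,
                       seed = if (!is.null(seed)) seed + 1L)
  list(data = data, params = params, design = design)
}

#' Write a simulated cohort to disk
#'
#' Writes the dataset in the package CSV dialect together with a JSON
#' sidecar of the generating parameters, for later recovery checks.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @param stem File name stem; writes `<stem>.csv` and
#'   `<stem>_params.json`.
#' @return Named character vector of the written paths, invisibly.
#' @export
save_cohort <- function(cohort, dir, stem = "cohort") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  csv <- file.path(dir, paste0(stem, ".csv"))
  json <- file.path(dir, paste0(stem, "_params.json"))
  write_ema(cohort$data, csv)
  write_parameter_set(cohort$params, json)
  inform(sprintf(
    "save_cohort: J = %d, N = %d, family = %s",
    cohort$design$n_patients, nrow(cohort$data), cohort$params$family))
  invisible(c(data = csv, params = json))
}
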