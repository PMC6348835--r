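#' Specify an ordinal model variant
#'
#' Four variants are available: cumulative (proportional-odds) or
#' stereotype logit, each with population-level slopes only
#' (`heterogeneous = FALSE`) or with patient-specific slopes drawn
#' around the population vector (`heterogeneous = TRUE`).
#'
#' @param family `"cumulative"` or `"stereotype"`.
#' @param heterogeneous Logical; include patient-specific slopes?
#' @param n_categories Number of outcome categories `C` (default 10).
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(family = c("cumulative", "stereotype"),
                       heterogeneous = FALSE, n_categories = 10) {
  family <- match.arg(family)
  if (n_categories < 2) {
    abort("`n_categories` must be at least 2", class = "ordema_argument_error")
  }
  structure(
    list(family = family, heterogeneous = isTRUE(heterogeneous),
         n_categories = as.integer(n_categories),
         n_predictors = length(ema_predictors)),
    class = "model_spec"
  )
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec> %s logit, %s slopes, C = %d\n", x$family,
              if (x$heterogeneous) "patient-specific" else "population",
              x$n_categories))
  invisible(x)
}

#' The four standard model variants
#'
#' @param n_categories Number of outcome categories.
#' @return A named list of [model_spec()] objects covering both families
#'   with and without patient-specific slopes.
#' @export
standard_model_specs <- function(n_categories = 10) {
  list(
    cumulative = model_spec("cumulative", FALSE, n_categories),
    cumulative_heterogeneous = model_spec("cumulative", TRUE, n_categories),
    stereotype = model_spec("stereotype", FALSE, n_categories),
    stereotype_heterogeneous = model_spec("stereotype", TRUE, n_categories)
  )
}

#' Prior configuration
#'
#' Weakly informative priors: each population slope has a normal prior
#' with mean +1 (mood, sleep, enjoyed activities, social contact) or -1
#' (worry) and variance `variance` (default 100, i.e. nearly flat).
#' Cutpoints/intercepts are normal(0, `variance`); patient slopes are
#' normal around the population slope with the same fixed variance; the
#' stereotype score increments follow a symmetric
#' Dirichlet(`dirichlet_concentration`).
#'
#' Setting `learn_heterogeneity_sd = TRUE` replaces the fixed spread of
#' the patient-slope hierarchy by per-predictor scales with a
#' half-normal(`heterogeneity_sd_prior`) prior; the default keeps the
#' spread fixed.
#'
#' @param slope_means Named 5-vector of prior means for the population
#'   slopes, in the order of [ema_predictors].
#' @param variance Prior variance sigma^2 shared by slopes and
#'   cutpoints.
#' @param dirichlet_concentration Concentration `A` of the symmetric
#'   Dirichlet on the stereotype score increments.
#' @param learn_heterogeneity_sd Learn the patient-slope spread instead
#'   of fixing it at `sqrt(variance)`?
#' @param heterogeneity_sd_prior Half-normal scale for the learned
#'   spread (ignored unless `learn_heterogeneity_sd = TRUE`).
#' @return An object of class `prior_config`.
#' @export
prior_config <- function(slope_means = c(mood = 1, worry = -1, sleep = 1,
                                         enjoyed_activities = 1,
                                         social_contact = 1),
                         variance = 100, dirichlet_concentration = 1,
                         learn_heterogeneity_sd = FALSE,
                         heterogeneity_sd_prior = 5) {
  if (length(slope_means) != length(ema_predictors)) {
    abort("`slope_means` must have one entry per predictor",
          class = "ordema_argument_error")
  }
  if (!is.numeric(variance) || variance <= 0) {
    abort("`variance` must be positive", class = "ordema_argument_error")
  }
  if (!is.numeric(dirichlet_concentration) || dirichlet_concentration <= 0) {
    abort("`dirichlet_concentration` must be positive",
          class = "ordema_argument_error")
  }
  structure(
    list(slope_means = setNames(as.numeric(slope_means), ema_predictors),
         variance = variance,
         dirichlet_concentration = dirichlet_concentration,
         learn_heterogeneity_sd = isTRUE(learn_heterogeneity_sd),
         heterogeneity_sd_prior = heterogeneity_sd_prior),
    class = "prior_config"
  )
}

#' Category probabilities of the cumulative (proportional-odds) model
#'
#' The cumulative logit model sets `logit P(Y <= c) = alpha_c - x'b`
#' for `c = 1..C-1` with nondecreasing cutpoints `alpha`; category
#' probabilities are the successive differences, padded so that the
#' vector sums to one.
#'
#' @param x Numeric predictor vector (the five diary scores).
#' @param slopes Numeric slope vector of the same length as `x`.
#' @param cutpoints Nondecreasing numeric vector of length `C - 1`.
#' @return A probability vector of length `C`.
#' @export
olm_category_probs <- function(x, slopes, cutpoints) {
  if (length(x) != length(slopes)) {
    abort("`x` and `slopes` must have equal length",
          class = "ordema_argument_error")
  }
  if (is.unsorted(cutpoints)) {
    abort("`cutpoints` must be nondecreasing", class = "ordema_argument_error")
  }
  eta <- sum(x * slopes)
  q <- plogis(cutpoints - eta)
  p <- c(q[1], diff(q), 1 - q[length(q)])
  pmax(p, 0)
}

#' Category probabilities of the stereotype logit model
#'
#' The stereotype model sets `P(Y = c) proportional to
#' exp(alpha_c + phi_c * x'b)` with `alpha_1 = 0` and monotone scores
#' `0 = phi_1 <= ... <= phi_C = 1`. The softmax is computed with
#' max-subtraction for numerical stability.
#'
#' @inheritParams olm_category_probs
#' @param intercepts Numeric vector of length `C` with `intercepts[1] = 0`.
#' @param scores Numeric vector of length `C`: nondecreasing, starting
#'   at 0 and ending at 1.
#' @return A probability vector of length `C`.
#' @export
stereotype_category_probs <- function(x, slopes, intercepts, scores) {
  if (length(x) != length(slopes)) {
    abort("`x` and `slopes` must have equal length",
          class = "ordema_argument_error")
  }
  if (length(intercepts) != length(scores)) {
    abort("`intercepts` and `scores` must have equal length",
          class = "ordema_argument_error")
  }
  if (intercepts[1] != 0) {
    abort("`intercepts[1]` must be 0", class = "ordema_argument_error")
  }
  C <- length(scores)
  if (scores[1] != 0 || abs(scores[C] - 1) > 1e-9 || is.unsorted(scores)) {
    abort("`scores` must be nondecreasing with scores[1] = 0, scores[C] = 1",
          class = "ordema_argument_error")
  }
  s <- intercepts + scores * sum(x * slopes)
  e <- exp(s - max(s))
  e / sum(e)
}

#' Stereotype scores from a Dirichlet simplex
#'
#' Builds the monotone score vector `phi` as the cumulative sum of a
#' length `C - 1` simplex `gamma`: `phi_1 = 0`,
#' `phi_c = sum(gamma[1:(c-1)])`, and `phi_C` forced to exactly 1.
#'
#' @param gamma Nonnegative vector summing to 1 (within 1e-9).
#' @return Score vector `phi` of length `length(gamma) + 1`.
#' @export
phi_from_gamma <- function(gamma) {
  if (any(gamma < 0) || abs(sum(gamma) - 1) > 1e-9) {
    abort("`gamma` must be a simplex (nonnegative, summing to 1)",
          class = "ordema_argument_error")
  }
  phi <- c(0, cumsum(gamma))
  phi[length(phi)] <- 1
  phi
}

#' Construct a parameter set
#'
#' Bundles one realization of all model parameters and validates the
#' family's constraints: nondecreasing cutpoints for the cumulative
#' model; `alpha_1 = 0`, simplex `gamma` and monotone `phi` for the
#' stereotype model. For heterogeneous models `beta` is a `J x 5` matrix
#' whose rownames identify the patients.
#'
#' @param family `"cumulative"` or `"stereotype"`.
#' @param delta Population slope 5-vector.
#' @param alpha Cutpoints (length `C - 1`, cumulative) or intercepts
#'   (length `C` with `alpha[1] = 0`, stereotype).
#' @param beta Optional `J x 5` matrix of patient slopes.
#' @param gamma Stereotype simplex of length `C - 1` (required for the
#'   stereotype family; `phi` is derived from it).
#' @param n_categories Number of categories `C`.
#' @return An object of class `parameter_set`.
#' @export
parameter_set <- function(family = c("cumulative", "stereotype"), delta,
                          alpha, beta = NULL, gamma = NULL,
                          n_categories = 10) {
  family <- match.arg(family)
  C <- as.integer(n_categories)
  delta <- setNames(as.numeric(delta), ema_predictors)
  if (length(delta) != length(ema_predictors)) {
    abort("`delta` must have 5 components", class = "ordema_argument_error")
  }
  if (family == "cumulative") {
    if (length(alpha) != C - 1) {
      abort(paste0("cumulative `alpha` must have length C - 1 = ", C - 1),
            class = "ordema_argument_error")
    }
    if (is.unsorted(alpha)) {
      abort("cumulative cutpoints must be nondecreasing",
            class = "ordema_argument_error")
    }
    phi <- NULL
  } else {
    if (length(alpha) != C) {
      abort(paste0("stereotype `alpha` must have length C = ", C),
            class = "ordema_argument_error")
    }
    if (alpha[1] != 0) {
      abort("stereotype `alpha[1]` must be 0", class = "ordema_argument_error")
    }
    if (is.null(gamma) || length(gamma) != C - 1) {
      abort(paste0("stereotype `gamma` must have length C - 1 = ", C - 1),
            class = "ordema_argument_error")
    }
    phi <- phi_from_gamma(gamma)
  }
  if (!is.null(beta)) {
    beta <- as.matrix(beta)
    if (ncol(beta) != length(ema_predictors)) {
      abort("`beta` must have 5 columns", class = "ordema_argument_error")
    }
    colnames(beta) <- ema_predictors
  }
  structure(
    list(family = family, n_categories = C, delta = delta,
         alpha = as.numeric(alpha), beta = beta,
         gamma = if (is.null(gamma)) NULL else as.numeric(gamma), phi = phi),
    class = "parameter_set"
  )
}

#' @export
print.parameter_set <- function(x, ...) {
  cat(sprintf("<parameter_set> %s, C = %d, %s\n", x$family, x$n_categories,
              if (is.null(x$beta)) "population slopes only"
              else paste0("patient slopes for J = ", nrow(x$beta))))
  invisible(x)
}

#' Serialize a parameter set to JSON
#'
#' @param params A [parameter_set()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_parameter_set <- function(params, path) {
  out <- params[!vapply(params, is.null, logical(1))]
  if (!is.null(out$beta)) {
    out$beta_rownames <- rownames(params$beta)
    out$beta <- unname(as.matrix(params$beta))
  }
  extra <- setdiff(names(out), c("family", "n_categories", "delta", "alpha",
                                 "beta", "beta_rownames", "gamma", "phi"))
  out <- c(out[intersect(c("family", "n_categories", "delta", "alpha",
                           "beta", "beta_rownames", "gamma", "phi"),
                         names(out))],
           out[extra])
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_parameter_set
#' @export
read_parameter_set <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  beta <- if (!is.null(raw$beta)) {
    b <- as.matrix(raw$beta)
    if (!is.null(raw$beta_rownames)) rownames(b) <- raw$beta_rownames
    b
  }
  parameter_set(
    family = raw$family, delta = raw$delta, alpha = raw$alpha, beta = beta,
    gamma = raw$gamma, n_categories = raw$n_categories
  )
}

# -- internal vectorized likelihood pieces ----------------------------------

# per-record log P(y | eta) for the cumulative model: the log of the
# logistic-CDF difference, floored to keep the tail finite
.cum_loglik <- function(y, eta, alpha) {
  C <- length(alpha) + 1
  ll <- numeric(length(y))
  lo <- y == 1
  hi <- y == C
  mid <- !(lo | hi)
  if (any(lo)) ll[lo] <- log(plogis(alpha[1] - eta[lo]))
  if (any(hi)) ll[hi] <- log(1 - plogis(alpha[C - 1] - eta[hi]))
  if (any(mid)) {
    p <- plogis(alpha[y[mid]] - eta[mid]) -
      plogis(alpha[y[mid] - 1] - eta[mid])
    ll[mid] <- log(p)
  }
  pmax(ll, -745)
}

# stable per-record log P(y | eta) for the stereotype model
.ste_loglik <- function(y, eta, alpha, phi) {
  S <- outer(eta, phi) + matrix(alpha, length(eta), length(alpha),
                                byrow = TRUE)
  m <- do.call(pmax, c(as.data.frame(S), list(na.rm = FALSE)))
  lse <- m + log(rowSums(exp(S - m)))
  S[cbind(seq_along(y), y)] - lse
}

# N x C matrix of category probabilities, vectorized over records
.prob_matrix <- function(family, eta, alpha, phi = NULL) {
  if (family == "cumulative") {
    C <- length(alpha) + 1
    q <- plogis(outer(alpha, eta, function(a, e) a - e))  # (C-1) x N
    p <- rbind(q[1, , drop = FALSE],
               if (C > 2) q[-1, , drop = FALSE] - q[-(C - 1), , drop = FALSE],
               1 - q[C - 1, , drop = FALSE])
    t(pmax(p, 0))
  } else {
    S <- outer(eta, phi) + matrix(alpha, length(eta), length(alpha),
                                  byrow = TRUE)
    S <- S - do.call(pmax, as.data.frame(S))
    E <- exp(S)
    E / rowSums(E)
  }
}

# map a complete diary tibble onto the matrices used by the samplers
.model_frame <- function(data, n_categories) {
  score_cols <- c(ema_predictors, "self_esteem")
  if (anyNA(data[, score_cols])) {
    abort("data contains missing scores; apply filter_complete() first",
          class = "ordema_argument_error")
  }
  pid <- factor(data$patient_id, levels = unique(data$patient_id))
  list(
    X = as.matrix(data[, ema_predictors]),
    y = as.integer(data$self_esteem),
    pid = as.integer(pid),
    patients = levels(pid),
    J = nlevels(pid),
    N = nrow(data),
    C = as.integer(n_categories)
  )
}

# per-record eta given a parameter set (patient slopes when available)
.eta_for <- function(spec, params, mf) {
  if (spec$heterogeneous) {
    beta <- params$beta
    if (is.null(beta)) {
      abort("heterogeneous spec requires patient slopes `beta`",
            class = "ordema_argument_error")
    }
    rows <- if (!is.null(rownames(beta))) {
      idx <- match(mf$patients, rownames(beta))
      if (anyNA(idx)) {
        abort(paste0("patient `", mf$patients[which(is.na(idx))[1]],
                     "` has no row in `beta`"),
              class = "ordema_argument_error")
      }
      idx
    } else {
      if (nrow(beta) < mf$J) {
        abort("`beta` has fewer rows than patients in the data",
              class = "ordema_argument_error")
      }
      seq_len(mf$J)
    }
    B <- beta[rows, , drop = FALSE]
    rowSums(mf$X * B[mf$pid, , drop = FALSE])
  } else {
    as.numeric(mf$X %*% params$delta)
  }
}

#' Pointwise log-likelihood of a parameter set
#'
#' Evaluates `log P(Y_jt | x_jt, params)` for every record: the log of
#' the observed category's probability under the model family, using
#' the patient's slope row for heterogeneous specs and the population
#' slopes otherwise.
#'
#' @param spec A [model_spec()].
#' @param params A [parameter_set()] dimensioned for the data.
#' @param data A complete diary tibble (see [filter_complete()]).
#' @return Numeric vector of length `nrow(data)`.
#' @export
pointwise_log_lik <- function(spec, params, data) {
  mf <- .model_frame(data, spec$n_categories)
  eta <- .eta_for(spec, params, mf)
  if (spec$family == "cumulative") {
    .cum_loglik(mf$y, eta, params$alpha)
  } else {
    .ste_loglik(mf$y, eta, params$alpha, params$phi)
  }
}

#' Log prior density of a parameter set
#'
#' Sums the closed-form log densities of the hierarchical prior:
#' normal(`mu`, sigma^2) for each population slope, normal(0, sigma^2)
#' for each free cutpoint/intercept, normal(delta, sigma^2) for each
#' patient-slope row (heterogeneous specs only) and a symmetric
#' Dirichlet for the stereotype simplex. Parameter sets that violate
#' their constraints have zero prior support and return `-Inf` (with a
#' message).
#'
#' @param spec A [model_spec()].
#' @param prior A [prior_config()].
#' @param params A [parameter_set()].
#' @return A scalar log density.
#' @export
log_prior_density <- function(spec, prior, params) {
  sigma <- sqrt(prior$variance)
  C <- spec$n_categories
  bad <- function(msg) {
    inform(paste0("log_prior_density: ", msg, "; returning -Inf"))
    -Inf
  }
  if (params$family != spec$family) {
    return(bad("parameter family does not match the model specification"))
  }
  lp <- sum(dnorm(params$delta, prior$slope_means, sigma, log = TRUE))
  if (spec$family == "cumulative") {
    if (length(params$alpha) != C - 1) return(bad("alpha has wrong length"))
    if (is.unsorted(params$alpha)) return(bad("cutpoints are not ordered"))
    lp <- lp + sum(dnorm(params$alpha, 0, sigma, log = TRUE))
  } else {
    if (length(params$alpha) != C) return(bad("alpha has wrong length"))
    if (params$alpha[1] != 0) return(bad("stereotype alpha[1] must be 0"))
    lp <- lp + sum(dnorm(params$alpha[-1], 0, sigma, log = TRUE))
    g <- params$gamma
    if (is.null(g) || length(g) != C - 1 || any(g < 0) ||
        abs(sum(g) - 1) > 1e-9) {
      return(bad("gamma is not a simplex of length C - 1"))
    }
    A <- prior$dirichlet_concentration
    lp <- lp + lgamma(A * (C - 1)) - (C - 1) * lgamma(A) +
      sum((A - 1) * log(pmax(g, 1e-300)))
  }
  if (spec$heterogeneous) {
    if (is.null(params$beta)) return(bad("heterogeneous spec needs beta"))
    lp <- lp + sum(dnorm(t(params$beta), params$delta, sigma, log = TRUE))
  }
  lp
}
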