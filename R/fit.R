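#' MCMC configuration
#'
#' The default mirrors the reference analysis profile: 4 chains of
#' 60,000 iterations each, the second half retained and every twentieth
#' draw stored (1,500 draws per chain). [desk_profile()] is a reduced
#' preset for interactive work and tests.
#'
#' @param chains Number of chains.
#' @param iterations Total iterations per chain (warmup plus sampling).
#' @param post_warmup Number of post-warmup iterations per chain.
#' @param thin Keep every `thin`-th post-warmup draw.
#' @param seed Optional integer seed; each chain uses a deterministic
#'   offset of it.
#' @param target_accept Dual-averaging acceptance target of the sampler.
#' @param max_leapfrog Upper bound of the jittered leapfrog path length.
#' @return An object of class `mcmc_config`.
#' @export
mcmc_config <- function(chains = 4, iterations = 60000, post_warmup = 30000,
                        thin = 20, seed = NULL, target_accept = 0.8,
                        max_leapfrog = 32) {
  if (chains < 1) abort("`chains` must be >= 1", class = "ordema_argument_error")
  if (thin < 1) abort("`thin` must be >= 1", class = "ordema_argument_error")
  if (post_warmup > iterations) {
    abort("`post_warmup` cannot exceed `iterations`",
          class = "ordema_argument_error")
  }
  if (post_warmup < thin) {
    abort("`post_warmup` must allow at least one stored draw",
          class = "ordema_argument_error")
  }
  structure(
    list(chains = as.integer(chains), iterations = as.integer(iterations),
         post_warmup = as.integer(post_warmup), thin = as.integer(thin),
         seed = seed, target_accept = target_accept,
         max_leapfrog = as.integer(max_leapfrog)),
    class = "mcmc_config"
  )
}

#' @rdname mcmc_config
#' @export
desk_profile <- function(chains = 4, iterations = 2000, post_warmup = 1000,
                         thin = 1, seed = NULL, target_accept = 0.8,
                         max_leapfrog = 32) {
  mcmc_config(chains, iterations, post_warmup, thin, seed, target_accept,
              max_leapfrog)
}

# -- unconstrained parameter vector layout ----------------------------------

.theta_layout <- function(spec, J, prior) {
  C <- spec$n_categories
  K <- spec$n_predictors
  het <- spec$heterogeneous
  learn <- het && isTRUE(prior$learn_heterogeneity_sd)
  n_head <- if (spec$family == "cumulative") C - 1 else 2 * C - 3
  dim <- n_head + K + if (het) J * K else 0
  if (learn) dim <- dim + K
  list(C = C, K = K, J = J, het = het, learn = learn,
       family = spec$family, n_head = n_head,
       idx_delta = n_head + seq_len(K),
       idx_beta = if (het) n_head + K + seq_len(J * K),
       idx_tau = if (learn) n_head + K + J * K + seq_len(K),
       dim = dim)
}

# unconstrained vector -> constrained parameter pieces
.constrain <- function(lay, theta, patients = NULL) {
  C <- lay$C
  K <- lay$K
  if (lay$family == "cumulative") {
    alpha <- cumsum(c(theta[1], exp(theta[seq_len(C - 2) + 1])))
    gamma <- NULL
    phi <- NULL
  } else {
    alpha <- c(0, theta[seq_len(C - 1)])
    z <- c(theta[(C - 1) + seq_len(C - 2)], 0)
    gamma <- exp(z - max(z))
    gamma <- gamma / sum(gamma)
    phi <- phi_from_gamma(gamma)
  }
  delta <- setNames(theta[lay$idx_delta], ema_predictors)
  beta <- NULL
  if (lay$het) {
    beta <- matrix(theta[lay$idx_beta], lay$J, K, byrow = TRUE)
    dimnames(beta) <- list(patients, ema_predictors)
  }
  tau <- if (lay$learn) setNames(exp(theta[lay$idx_tau]), ema_predictors)
  list(alpha = alpha, gamma = gamma, phi = phi, delta = delta, beta = beta,
       tau = tau)
}

# constrained pieces -> unconstrained vector (used for inits and tests)
.unconstrain <- function(lay, pieces) {
  head <- if (lay$family == "cumulative") {
    a <- pieces$alpha
    c(a[1], log(pmax(diff(a), 1e-8)))
  } else {
    g <- pmax(pieces$gamma, 1e-8)
    z <- log(g / g[length(g)])
    c(pieces$alpha[-1], z[-length(z)])
  }
  out <- c(head, pieces$delta,
           if (lay$het) as.numeric(t(pieces$beta)),
           if (lay$learn) log(pieces$tau))
  unname(out)
}

# data-derived initial values, jittered per chain
.init_theta <- function(lay, mf, prior, prior_only, chain) {
  C <- lay$C
  if (prior_only || is.null(mf)) {
    alpha0 <- seq(-2, 2, length.out = max(C - 1, 2))[seq_len(C - 1)]
    freq <- rep(1 / C, C)
  } else {
    freq <- tabulate(mf$y, nbins = C) + 0.5
    freq <- freq / sum(freq)
    cum <- cumsum(freq)[seq_len(C - 1)]
    alpha0 <- qlogis(pmin(pmax(cum, 1e-4), 1 - 1e-4))
  }
  head <- if (lay$family == "cumulative") {
    c(alpha0[1], log(pmax(diff(alpha0), 0.05)))
  } else {
    rep(0, 2 * C - 3)  # alpha_2..C = 0, z = 0 (uniform scores)
  }
  theta <- c(head, rep(0, lay$K),
             if (lay$het) rep(0, lay$J * lay$K),
             if (lay$learn) rep(0, lay$K))
  theta + rnorm(length(theta), 0, 0.05)
}

#' Fit an ordinal model by Hamiltonian Monte Carlo
#'
#' Samples the posterior of a [model_spec()] under the [prior_config()]
#' hierarchy with the package's built-in HMC sampler (leapfrog
#' integrator, dual-averaging step-size adaptation, diagonal mass
#' matrix). Cutpoints are sampled through an order-preserving
#' log-increment transform and the stereotype simplex through an
#' additive log-ratio transform, so every stored draw satisfies the
#' model constraints by construction. The pointwise log-likelihood of
#' every stored draw is computed and kept for DIC/WAIC.
#'
#' @param data A complete diary tibble (see [filter_complete()]).
#' @param spec A [model_spec()].
#' @param prior A [prior_config()].
#' @param mcmc An [mcmc_config()]; defaults to the reduced
#'   [desk_profile()].
#' @param prior_only Suppress the likelihood and sample the prior
#'   (used to check the prior implementation).
#' @return An object of class `ordema_fit` with elements `draws`
#'   (tibble of constrained draws, one column per scalar parameter plus
#'   `.chain`/`.iteration`), `loglik` (draws x N matrix), `spec`,
#'   `prior`, `mcmc`, `patients` and sampler `diagnostics`.
#' @export
fit_ordinal <- function(data, spec, prior = prior_config(),
                        mcmc = desk_profile(), prior_only = FALSE) {
  if (is.null(data) || nrow(data) == 0) {
    abort("`data` is empty", class = "ordema_argument_error")
  }
  data <- validate_ema(data, n_categories = spec$n_categories)
  mf <- .model_frame(data, spec$n_categories)
  lay <- .theta_layout(spec, mf$J, prior)
  fam_code <- if (spec$family == "cumulative") 0L else 1L

  run_chain <- function(chain) {
    run <- function() {
      init <- .init_theta(lay, mf, prior, prior_only, chain)
      .hmc_run_chain(
        y = mf$y, X = mf$X, pid0 = mf$pid - 1L, J = mf$J, C = mf$C,
        family = fam_code, heterogeneous = spec$heterogeneous,
        prior_only = prior_only, learn_tau = lay$learn,
        prior_mu = unname(prior$slope_means), sigma2 = prior$variance,
        dirichlet_a = prior$dirichlet_concentration,
        tau0sd = prior$heterogeneity_sd_prior,
        iter = mcmc$iterations,
        warmup = mcmc$iterations - mcmc$post_warmup, thin = mcmc$thin,
        init = init, target_accept = mcmc$target_accept,
        max_leapfrog = mcmc$max_leapfrog
      )
    }
    if (!is.null(mcmc$seed)) {
      withr::with_seed((mcmc$seed * 1000 + chain) %% 2147483647, run())
    } else {
      run()
    }
  }

  t0 <- Sys.time()
  chains <- lapply(seq_len(mcmc$chains), run_chain)
  theta <- do.call(rbind, lapply(chains, `[[`, "draws"))
  n_per_chain <- nrow(chains[[1]]$draws)
  chain_id <- rep(seq_len(mcmc$chains), each = n_per_chain)

  draws <- .constrain_draws(lay, theta, mf$patients)
  draws <- dplyr::bind_cols(
    tibble::tibble(.chain = chain_id,
                   .iteration = rep(seq_len(n_per_chain), mcmc$chains)),
    draws
  )

  loglik <- NULL
  if (!prior_only) {
    loglik <- matrix(NA_real_, nrow(theta), mf$N)
    for (s in seq_len(nrow(theta))) {
      pieces <- .constrain(lay, theta[s, ], mf$patients)
      eta <- if (lay$het) {
        rowSums(mf$X * pieces$beta[mf$pid, , drop = FALSE])
      } else {
        as.numeric(mf$X %*% pieces$delta)
      }
      loglik[s, ] <- if (spec$family == "cumulative") {
        .cum_loglik(mf$y, eta, pieces$alpha)
      } else {
        .ste_loglik(mf$y, eta, pieces$alpha, pieces$phi)
      }
    }
  }

  structure(
    list(
      draws = draws, theta = theta, loglik = loglik, spec = spec,
      prior = prior, mcmc = mcmc, prior_only = prior_only,
      patients = mf$patients, data = data, layout = lay,
      diagnostics = tibble::tibble(
        chain = seq_len(mcmc$chains),
        accept_rate = vapply(chains, `[[`, numeric(1), "accept_rate"),
        divergences = vapply(chains, function(ch)
          as.numeric(ch$divergences), numeric(1)),
        step_size = vapply(chains, `[[`, numeric(1), "step_size")
      ),
      elapsed = as.numeric(difftime(Sys.time(), t0, units = "secs"))
    ),
    class = "ordema_fit"
  )
}

# name and assemble the constrained draws tibble
.constrain_draws <- function(lay, theta, patients) {
  C <- lay$C
  K <- lay$K
  cols <- list()
  if (lay$family == "cumulative") {
    alpha <- t(apply(theta[, seq_len(C - 1), drop = FALSE], 1, function(r) {
      cumsum(c(r[1], exp(r[-1])))
    }))
    if (C == 2) alpha <- matrix(theta[, 1], ncol = 1)
    colnames(alpha) <- paste0("alpha[", seq_len(C - 1), "]")
    cols$alpha <- alpha
  } else {
    alpha <- cbind(0, theta[, seq_len(C - 1), drop = FALSE])
    colnames(alpha) <- paste0("alpha[", seq_len(C), "]")
    z <- cbind(theta[, (C - 1) + seq_len(C - 2), drop = FALSE], 0)
    g <- exp(z - apply(z, 1, max))
    g <- g / rowSums(g)
    colnames(g) <- paste0("gamma[", seq_len(C - 1), "]")
    phi <- cbind(0, t(apply(g, 1, cumsum)))
    phi[, C] <- 1
    colnames(phi) <- paste0("phi[", seq_len(C), "]")
    cols$alpha <- alpha
    cols$gamma <- g
    cols$phi <- phi
  }
  delta <- theta[, lay$idx_delta, drop = FALSE]
  colnames(delta) <- paste0("delta[", ema_predictors, "]")
  cols$delta <- delta
  if (lay$het) {
    beta <- theta[, lay$idx_beta, drop = FALSE]
    colnames(beta) <- paste0(
      "beta[", rep(patients, each = K), ",", rep(ema_predictors, lay$J), "]")
    cols$beta <- beta
  }
  if (lay$learn) {
    tau <- exp(theta[, lay$idx_tau, drop = FALSE])
    colnames(tau) <- paste0("tau[", ema_predictors, "]")
    cols$tau <- tau
  }
  tibble::as_tibble(do.call(cbind, unname(cols)))
}

#' @export
print.ordema_fit <- function(x, ...) {
  cat(sprintf("<ordema_fit> %s logit, %s slopes%s\n", x$spec$family,
              if (x$spec$heterogeneous) "patient-specific" else "population",
              if (x$prior_only) " (prior only)" else ""))
  cat(sprintf("  %d chains x %d stored draws; %d observations, %d patients\n",
              x$mcmc$chains, nrow(x$draws) / x$mcmc$chains,
              nrow(x$data), length(x$patients)))
  cat(sprintf("  divergences: %d; mean acceptance: %.2f; %.1f s\n",
              sum(x$diagnostics$divergences),
              mean(x$diagnostics$accept_rate), x$elapsed))
  invisible(x)
}

# pooled draws matrix of the constrained parameters (no .chain/.iteration)
.draw_matrix <- function(fit) {
  as.matrix(fit$draws[, setdiff(names(fit$draws), c(".chain", ".iteration"))])
}

#' Posterior parameter summaries
#'
#' Per scalar parameter: the posterior median and a central credible
#' interval of the pooled draws, plus a significance flag (interval
#' excludes zero). The interval is equal-tailed by default; `"hdi"`
#' selects the narrowest interval containing the requested mass.
#'
#' @param fit An [fit_ordinal()] result.
#' @param interval Interval probability (default 0.95).
#' @param method `"eti"` (equal-tailed, default) or `"hdi"`.
#' @param include_patients Include the per-patient slope draws?
#' @return A tibble with columns `term`, `median`, `conf.low`,
#'   `conf.high`, `significant`.
#' @export
summarize_parameters <- function(fit, interval = 0.95,
                                 method = c("eti", "hdi"),
                                 include_patients = FALSE) {
  method <- match.arg(method)
  if (interval <= 0 || interval >= 1) {
    abort("`interval` must be in (0, 1)", class = "ordema_argument_error")
  }
  draws <- .draw_matrix(fit)
  if (nrow(draws) < 2) {
    abort("at least 2 draws are required", class = "ordema_argument_error")
  }
  if (!include_patients) {
    draws <- draws[, !grepl("^beta\\[", colnames(draws)), drop = FALSE]
  }
  lo_p <- (1 - interval) / 2
  summ <- apply(draws, 2, function(v) {
    if (method == "eti") {
      ci <- unname(quantile(v, c(lo_p, 1 - lo_p)))
    } else {
      s <- sort(v)
      n <- length(s)
      w <- max(1, ceiling(interval * n) - 1)
      i <- which.min(s[(1 + w):n] - s[seq_len(n - w)])
      ci <- c(s[i], s[i + w])
    }
    c(median(v), ci)
  })
  tibble::tibble(
    term = colnames(draws),
    median = unname(summ[1, ]),
    conf.low = unname(summ[2, ]),
    conf.high = unname(summ[3, ]),
    significant = unname(!(summ[2, ] <= 0 & summ[3, ] >= 0))
  )
}

#' @export
tidy.ordema_fit <- function(x, interval = 0.95, method = "eti",
                            include_patients = FALSE, ...) {
  out <- summarize_parameters(x, interval = interval, method = method,
                              include_patients = include_patients)
  dplyr::rename(out, estimate = "median")
}

#' @export
glance.ordema_fit <- function(x, ...) {
  diag <- convergence_diagnostics(x)
  tibble::tibble(
    n_obs = nrow(x$data),
    n_patients = length(x$patients),
    n_draws = nrow(x$draws),
    n_chains = x$mcmc$chains,
    divergences = sum(x$diagnostics$divergences),
    max_rhat = suppressWarnings(max(diag$rhat, na.rm = TRUE)),
    dic = if (x$prior_only) NA_real_ else dic(x)$dic,
    waic = if (x$prior_only) NA_real_ else waic(x)$waic
  )
}

#' Split-Rhat and effective sample size per parameter
#'
#' Rank-normalized split-Rhat (each chain halved, pooled ranks mapped
#' through the normal quantile function) and an effective sample size
#' from the summed per-chain autocorrelation estimate. Parameters with
#' Rhat above the threshold, or with degenerate (constant) chains, are
#' flagged.
#'
#' @param fit An [fit_ordinal()] result with at least 4 draws per chain.
#' @param rhat_threshold Flagging threshold (default 1.05).
#' @return A tibble with one row per scalar parameter: `term`, `rhat`,
#'   `ess`, `flagged`.
#' @export
convergence_diagnostics <- function(fit, rhat_threshold = 1.05) {
  draws <- .draw_matrix(fit)
  chain <- fit$draws$.chain
  n_chain <- length(unique(chain))
  if (n_chain < 2) {
    warn("single chain: split-Rhat uses the two half-chains only")
  }
  per_chain <- nrow(draws) / n_chain
  if (per_chain < 4) {
    abort("at least 4 draws per chain are required",
          class = "ordema_argument_error")
  }
  half <- rep(rep(1:2, each = ceiling(per_chain / 2))[seq_len(per_chain)],
              n_chain)
  grp <- interaction(chain, half, drop = TRUE)
  res <- apply(draws, 2, function(v) {
    if (var(v) == 0 || !all(is.finite(v))) return(c(NA_real_, 0))
    # rank-normalize, then classic split-Rhat
    z <- qnorm((rank(v) - 3 / 8) / (length(v) + 1 / 4))
    m <- tapply(z, grp, mean)
    s2 <- tapply(z, grp, var)
    n <- length(z) / nlevels(grp)
    W <- mean(s2)
    B <- n * var(as.numeric(m))
    rhat <- sqrt((n - 1) / n + B / (W * n))
    ess <- sum(tapply(v, chain, function(ch) {
      as.numeric(coda::effectiveSize(ch))
    }))
    c(rhat, ess)
  })
  tibble::tibble(
    term = colnames(draws),
    rhat = unname(res[1, ]),
    ess = unname(res[2, ]),
    flagged = unname(is.na(res[1, ]) | res[1, ] > rhat_threshold)
  )
}

#' Export posterior draws as CSV and diagnostics as JSON
#'
#' @param fit An [fit_ordinal()] result.
#' @param draws_path CSV destination (one row per draw, one column per
#'   scalar parameter).
#' @param diagnostics_path Optional JSON destination for sampler and
#'   convergence diagnostics.
#' @return `draws_path`, invisibly.
#' @export
export_draws <- function(fit, draws_path, diagnostics_path = NULL) {
  readr::write_csv(fit$draws, draws_path)
  if (!is.null(diagnostics_path)) {
    jsonlite::write_json(
      list(sampler = fit$diagnostics,
           convergence = convergence_diagnostics(fit)),
      diagnostics_path, dataframe = "rows", auto_unbox = TRUE, digits = NA
    )
  }
  invisible(draws_path)
}
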