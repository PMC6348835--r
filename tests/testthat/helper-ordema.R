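# fixtures built in code; all randomness is seeded at the call sites

toy_ema <- function(n = 6, patients = c("A", "A", "A", "B", "B", "C")) {
  patients <- rep_len(patients, n)
  tibble::tibble(
    patient_id = patients,
    time_index = as.integer(stats::ave(seq_len(n), patients, FUN = seq_along)),
    mood = rep_len(c(5, 7, 3, 8, 2, 6), n),
    worry = rep_len(c(2, 4, 9, 1, 6, 3), n),
    sleep = rep_len(c(6, 5, 4, 7, 8, 2), n),
    enjoyed_activities = rep_len(c(4, 6, 2, 9, 5, 7), n),
    social_contact = rep_len(c(3, 8, 5, 6, 1, 4), n),
    self_esteem = rep_len(c(5, 8, 2, 9, 3, 6), n)
  )
}

# a small simulated cohort for fitting tests
small_cohort <- function(seed, J = 12, n_per = 12,
                         family = "cumulative", het_sd = 1) {
  des <- cohort_design(n_patients = J, obs_per_patient = n_per, seed = seed)
  simulate_cohort(des, family, heterogeneity_sd = het_sd, seed = seed)
}

# fast MCMC settings for smoke tests
tiny_mcmc <- function(seed = 1, chains = 2) {
  mcmc_config(chains = chains, iterations = 600, post_warmup = 300,
              thin = 1, seed = seed)
}

# reduced settings used for the heterogeneity-detection experiments
reduced_mcmc <- function(seed = 1) {
  mcmc_config(chains = 2, iterations = 1500, post_warmup = 750, thin = 1,
              seed = seed)
}

# build an `ordema_fit`-shaped object from a draws tibble (no data/theta),
# enough for summaries and diagnostics
fake_fit <- function(draws_tbl, chains = length(unique(draws_tbl$.chain))) {
  structure(
    list(draws = draws_tbl, theta = NULL, loglik = NULL,
         spec = model_spec("cumulative"), prior = prior_config(),
         mcmc = NULL, prior_only = TRUE, patients = character(),
         data = NULL, layout = NULL,
         diagnostics = tibble::tibble(chain = seq_len(chains),
                                      accept_rate = NA_real_,
                                      divergences = 0, step_size = NA_real_)),
    class = "ordema_fit"
  )
}

# random valid parameter draws for property tests
random_cumulative_pars <- function(C) {
  list(slopes = rnorm(5, 0, 0.5), cutpoints = sort(rnorm(C - 1, 0, 3)))
}

random_stereotype_pars <- function(C) {
  g <- rgamma(C - 1, 1)
  list(slopes = rnorm(5, 0, 0.5),
       intercepts = c(0, rnorm(C - 1, 0, 2)),
       scores = phi_from_gamma(g / sum(g)))
}
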