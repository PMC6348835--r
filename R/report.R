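#' Cross-validated comparison of several models
#'
#' Runs [cross_validate()] for every supplied spec on identical fold
#' splits, assembles the model-comparison table (RMSE, MAE, DIC, WAIC
#' per model plus the two mean baselines), pairwise Wilcoxon tests on
#' the absolute error vectors of all models and baselines, and the
#' parameter summary of the best model (lowest value of
#' `select_by`, WAIC by default) refitted on the full data.
#'
#' @param data A complete diary tibble.
#' @param specs Named list of [model_spec()] objects (default: the four
#'   [standard_model_specs()]).
#' @param prior A [prior_config()].
#' @param k Number of CV folds.
#' @param mcmc An [mcmc_config()].
#' @param fold_seed Optional integer seed shared by all models' splits.
#' @param rule Point-prediction rule.
#' @param select_by `"waic"` or `"dic"`: measure used to pick the best
#'   model.
#' @return An object of class `ordema_eval` with `comparison` (the
#'   model-comparison tibble), `wilcoxon`, `best_model`,
#'   `best_parameters` (tibble of median, 2.5% and 97.5% bounds and
#'   significance flags) and the per-model `ordema_cv` results in
#'   `cv`.
#' @export
evaluate_models <- function(data, specs = standard_model_specs(),
                            prior = prior_config(), k = 10,
                            mcmc = desk_profile(), fold_seed = NULL,
                            rule = c("median", "mode"),
                            select_by = c("waic", "dic")) {
  rule <- match.arg(rule)
  select_by <- match.arg(select_by)
  if (length(specs) < 1) {
    abort("at least one model spec is required",
          class = "ordema_argument_error")
  }
  if (is.null(names(specs))) {
    names(specs) <- vapply(specs, function(s)
      paste0(s$family, if (s$heterogeneous) "_heterogeneous" else ""),
      character(1))
  }
  cv <- vector("list", length(specs))
  names(cv) <- names(specs)
  for (nm in names(specs)) {
    t0 <- Sys.time()
    cv[[nm]] <- cross_validate(data, specs[[nm]], prior, k, mcmc,
                               fold_seed = fold_seed, rule = rule)
    inform(sprintf("evaluate_models: %s done in %.1f s", nm,
                   as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  }

  model_rows <- dplyr::bind_rows(lapply(names(cv), function(nm) {
    r <- cv[[nm]]$metrics[1, ]
    r$model <- nm
    r
  }))
  base_rows <- cv[[1]]$metrics[-1, ]  # identical folds => identical baselines
  comparison <- dplyr::bind_rows(model_rows, base_rows)

  errs <- c(
    lapply(cv, function(x)
      abs(x$predictions$observed - x$predictions$predicted)),
    list(mean_model = abs(cv[[1]]$predictions$observed -
                            cv[[1]]$predictions$mean_model),
         mean_individual_model = abs(cv[[1]]$predictions$observed -
                                       cv[[1]]$predictions$mean_individual))
  )
  pairs <- utils::combn(names(errs), 2, simplify = FALSE)
  wil <- dplyr::bind_rows(lapply(pairs, function(pr) {
    dplyr::mutate(compare_errors_wilcoxon(errs[[pr[1]]], errs[[pr[2]]]),
                  model_a = pr[1], model_b = pr[2], .before = 1)
  }))

  crit <- model_rows[[select_by]]
  best <- model_rows$model[which.min(crit)]
  best_fit <- cv[[best]]$fit_full
  structure(
    list(comparison = comparison, wilcoxon = wil, cv = cv,
         best_model = best, best_fit = best_fit,
         best_parameters = summarize_parameters(best_fit),
         select_by = select_by, k = k, fold_seed = fold_seed),
    class = "ordema_eval"
  )
}

#' @export
print.ordema_eval <- function(x, ...) {
  cat("Model comparison (", x$k, "-fold patient-stratified CV)\n", sep = "")
  print(x$comparison)
  cat("\nBest model by ", x$select_by, ": ", x$best_model, "\n", sep = "")
  invisible(x)
}

#' Render the model-comparison table as Markdown
#'
#' Mirrors the measure-table layout: one row per model with RMSE, MAE,
#' DIC and WAIC, baselines last with `-` in the criterion columns.
#'
#' @param eval An [evaluate_models()] result (or an `ordema_cv`).
#' @return Character vector of Markdown lines.
#' @export
render_comparison_table <- function(eval) {
  tab <- if (inherits(eval, "ordema_eval")) eval$comparison else eval$metrics
  fmt <- function(v) ifelse(is.na(v), "-", sprintf("%.2f", v))
  c("| Model | RMSE | MAE | DIC | WAIC |",
    "|---|---|---|---|---|",
    sprintf("| %s | %.2f | %.2f | %s | %s |", tab$model, tab$rmse, tab$mae,
            fmt(tab$dic), fmt(tab$waic)))
}

#' Run the full evaluation pipeline and write its outputs
#'
#' End-to-end driver: validates and complete-case filters the input,
#' cross-validates every configured model, writes the comparison table
#' (CSV, JSON and Markdown), the Wilcoxon table, the best model's
#' parameter summary, the prediction and patient-slope figures, and a
#' manifest (configuration, seeds, package version) sufficient to
#' reproduce the run.
#'
#' @param data A diary tibble or path to a diary CSV.
#' @param output_dir Directory for the result files (created if
#'   needed).
#' @inheritParams evaluate_models
#' @param plots Write figure files?
#' @return The [evaluate_models()] result, invisibly.
#' @export
run_evaluation <- function(data, output_dir, specs = standard_model_specs(),
                           prior = prior_config(), k = 10,
                           mcmc = desk_profile(), fold_seed = NULL,
                           rule = c("median", "mode"),
                           select_by = c("waic", "dic"), plots = TRUE) {
  t0 <- Sys.time()
  if (is.character(data)) data <- read_ema(data)
  n_raw <- nrow(data)
  data <- filter_complete(data)
  inform(sprintf("run_evaluation: %d of %d records complete", nrow(data),
                 n_raw))
  if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)

  res <- evaluate_models(data, specs, prior, k, mcmc, fold_seed, rule,
                         select_by)

  readr::write_csv(res$comparison, file.path(output_dir, "model_comparison.csv"))
  jsonlite::write_json(res$comparison,
                       file.path(output_dir, "model_comparison.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  writeLines(render_comparison_table(res),
             file.path(output_dir, "model_comparison.md"))
  readr::write_csv(res$wilcoxon, file.path(output_dir, "wilcoxon_tests.csv"))
  readr::write_csv(res$best_parameters,
                   file.path(output_dir, "best_model_parameters.csv"))

  if (isTRUE(plots)) {
    best_cv <- res$cv[[res$best_model]]
    p1 <- plot_predictions(best_cv$predictions$observed,
                           best_cv$predictions$predicted)
    ggplot2::ggsave(file.path(output_dir, "predicted_vs_observed.png"), p1,
                    width = 8, height = 4, dpi = 150)
    if (res$best_fit$spec$heterogeneous) {
      p2 <- plot_patient_slopes(res$best_fit)
      ggplot2::ggsave(file.path(output_dir, "patient_slopes.png"), p2,
                      width = 10, height = 6, dpi = 150)
    }
  }

  manifest <- list(
    package = "ordema",
    version = as.character(packageVersion("ordema")),
    timestamp = format(Sys.time(), tz = "UTC"),
    n_obs = nrow(data), n_patients = length(unique(data$patient_id)),
    models = names(res$cv), k = k, rule = match.arg(rule),
    select_by = res$select_by, fold_seed = fold_seed,
    mcmc = unclass(mcmc), prior = unclass(prior),
    elapsed_seconds = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  inform(sprintf("run_evaluation: finished in %.1f s; best model: %s",
                 manifest$elapsed_seconds, res$best_model))
  invisible(res)
}

#' Read a run configuration file
#'
#' YAML or JSON (by extension) mirroring the [mcmc_config()] and
#' [prior_config()] fields plus `models`, `k`, `fold_seed` and `rule`.
#' Absent fields keep their defaults.
#'
#' @param path Configuration file path.
#' @return A list with elements `specs`, `prior`, `mcmc`, `k`,
#'   `fold_seed`, `rule`.
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  n_categories <- raw$n_categories %||% 10
  all_specs <- standard_model_specs(n_categories)
  model_names <- raw$models %||% names(all_specs)
  unknown <- setdiff(model_names, names(all_specs))
  if (length(unknown) > 0) {
    abort(paste0("Unknown model(s): ", paste(unknown, collapse = ", ")),
          class = "ordema_argument_error")
  }
  prior_args <- raw$prior %||% list()
  mcmc_args <- raw$mcmc %||% list()
  list(
    specs = all_specs[model_names],
    prior = do.call(prior_config, prior_args),
    mcmc = do.call(mcmc_config, c(
      mcmc_args[setdiff(names(mcmc_args), "desk_profile")],
      if (isTRUE(mcmc_args$desk_profile) &&
          is.null(mcmc_args$iterations)) {
        list(iterations = 2000, post_warmup = 1000, thin = 1)
      })),
    k = raw$k %||% 10,
    fold_seed = raw$fold_seed,
    rule = raw$rule %||% "median"
  )
}
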