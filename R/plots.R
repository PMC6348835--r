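#' Predicted-versus-observed figure
#'
#' Observed outcomes are sorted in ascending order (stable, so tied
#' observations keep their original relative order) and drawn as a
#' line; the paired point predictions are overlaid as crosses.
#'
#' @param observed,predicted Equal-length integer vectors.
#' @return A ggplot object.
#' @export
plot_predictions <- function(observed, predicted) {
  if (length(observed) != length(predicted)) {
    abort("`observed` and `predicted` must have equal length",
          class = "ordema_argument_error")
  }
  ord <- order(observed)  # stable
  df <- tibble::tibble(index = seq_along(observed),
                       observed = observed[ord],
                       predicted = predicted[ord])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$index)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$observed,
                                    colour = "observed")) +
    ggplot2::geom_point(ggplot2::aes(y = .data$predicted,
                                     colour = "predicted"),
                        shape = 4, alpha = 0.6) +
    ggplot2::scale_colour_manual(NULL,
                                 values = c(observed = "black",
                                            predicted = "#D55E00")) +
    ggplot2::labs(x = "test records (sorted by observed self-esteem)",
                  y = "self-esteem category") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.ordema_pred <- function(object, ...) {
  if (is.null(object$observed)) {
    abort("predictions carry no observed outcomes to plot against",
          class = "ordema_argument_error")
  }
  plot_predictions(object$observed, object$point)
}

#' Per-patient slope distributions
#'
#' One panel per predictor; within each panel the patients are ordered
#' by the posterior mean of their slope (independently per predictor),
#' and each patient's posterior is shown as its median with 50% and
#' 95% equal-tailed intervals. The horizontal zero line marks
#' no-effect: intervals clear of it indicate patients for whom the
#' predictor is individually significant.
#'
#' @param fit A heterogeneous [fit_ordinal()] result.
#' @return A ggplot object with five panels.
#' @export
plot_patient_slopes <- function(fit) {
  if (!fit$spec$heterogeneous) {
    abort(paste0("model has no per-patient slopes; fit a heterogeneous ",
                 "spec to plot them"),
          class = "ordema_argument_error")
  }
  draws <- .draw_matrix(fit)
  beta_cols <- grep("^beta\\[", colnames(draws), value = TRUE)
  long <- tibble::tibble(
    term = rep(beta_cols, each = nrow(draws)),
    value = as.numeric(draws[, beta_cols])
  ) |>
    tidyr::separate_wider_regex(
      "term", c("beta\\[", patient = "[^,]+", ",", predictor = "[^\\]]+",
                "\\]")) |>
    dplyr::group_by(.data$predictor, .data$patient) |>
    dplyr::summarise(
      mean = mean(.data$value),
      median = median(.data$value),
      q025 = quantile(.data$value, 0.025),
      q25 = quantile(.data$value, 0.25),
      q75 = quantile(.data$value, 0.75),
      q975 = quantile(.data$value, 0.975),
      .groups = "drop"
    ) |>
    dplyr::group_by(.data$predictor) |>
    dplyr::arrange(.data$mean, .by_group = TRUE) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::ungroup() |>
    dplyr::mutate(predictor = factor(.data$predictor,
                                     levels = ema_predictors))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$rank)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey40") +
    ggplot2::geom_linerange(ggplot2::aes(ymin = .data$q025,
                                         ymax = .data$q975),
                            colour = "grey65", linewidth = 0.3) +
    ggplot2::geom_linerange(ggplot2::aes(ymin = .data$q25,
                                         ymax = .data$q75),
                            colour = "#0072B2", linewidth = 0.7) +
    ggplot2::geom_point(ggplot2::aes(y = .data$median), size = 0.5) +
    ggplot2::facet_wrap(~predictor, nrow = 1, scales = "free_y") +
    ggplot2::labs(x = "patients (ordered by posterior mean, per panel)",
                  y = "patient-specific slope") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.ordema_fit <- function(object, ...) {
  if (object$spec$heterogeneous) {
    return(plot_patient_slopes(object))
  }
  summ <- summarize_parameters(object)
  summ <- summ[grepl("^delta\\[", summ$term), ]
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$term, y = .data$median)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey40") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$conf.low,
                                          ymax = .data$conf.high)) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "population slope (95% interval)") +
    ggplot2::theme_minimal()
}
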