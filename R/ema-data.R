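#' Read an EMA diary table from CSV
#'
#' Reads a long-format diary file with one row per patient-day and the
#' columns `patient_id`, `time_index`, the five predictor items
#' (`mood`, `worry`, `sleep`, `enjoyed_activities`, `social_contact`)
#' and the outcome `self_esteem`. All scores are integers on a
#' `1..n_categories` scale; empty cells and `"NA"` are read as missing.
#' Row order of the file is preserved.
#'
#' @param path Path to a CSV file with a header row.
#' @param n_categories Number of ordinal categories `C` (default 10).
#' @return A tibble with the columns listed above, validated by
#'   [validate_ema()].
#' @seealso [write_ema()], [filter_complete()], [ema_summary()]
#' @export
read_ema <- function(path, n_categories = 10) {
  if (!file.exists(path)) {
    abort(paste0("File not found: ", path), class = "ordema_io_error")
  }
  header <- names(readr::read_csv(path, n_max = 0, show_col_types = FALSE))
  missing_cols <- setdiff(ema_columns, header)
  if (length(missing_cols) > 0) {
    abort(
      paste0("Missing required column(s): ",
             paste(missing_cols, collapse = ", ")),
      class = "ordema_schema_error"
    )
  }
  data <- readr::read_csv(
    path,
    col_types = readr::cols(
      patient_id = readr::col_character(),
      .default = readr::col_double()
    ),
    na = c("", "NA"),
    show_col_types = FALSE
  )
  validate_ema(data, n_categories = n_categories)
}

#' Write an EMA diary table to CSV
#'
#' Missing values are written as `NA`, which [read_ema()] reads back as
#' missing, so write/read round-trips are the identity on valid tables.
#'
#' @param data A diary tibble with the columns in [ema_columns].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ema <- function(data, path) {
  missing_cols <- setdiff(ema_columns, names(data))
  if (length(missing_cols) > 0) {
    abort(
      paste0("Missing required column(s): ",
             paste(missing_cols, collapse = ", ")),
      class = "ordema_schema_error"
    )
  }
  readr::write_csv(data[, ema_columns], path, na = "NA")
  invisible(path)
}

#' Validate an EMA diary table
#'
#' Checks the schema (all required columns present), the score range
#' (every non-missing score is an integer in `1..n_categories`) and the
#' uniqueness of `time_index` within each patient. Errors name the
#' offending column and row.
#'
#' @inheritParams write_ema
#' @param n_categories Number of ordinal categories `C`.
#' @return The validated data as a tibble, invisibly usable in pipes.
#' @export
validate_ema <- function(data, n_categories = 10) {
  if (n_categories < 2) {
    abort("`n_categories` must be at least 2", class = "ordema_argument_error")
  }
  missing_cols <- setdiff(ema_columns, names(data))
  if (length(missing_cols) > 0) {
    abort(
      paste0("Missing required column(s): ",
             paste(missing_cols, collapse = ", ")),
      class = "ordema_schema_error"
    )
  }
  data <- tibble::as_tibble(data)
  score_cols <- c(ema_predictors, "self_esteem")
  for (col in score_cols) {
    v <- data[[col]]
    if (!is.numeric(v)) {
      abort(paste0("Column `", col, "` must be numeric"),
            class = "ordema_validation_error")
    }
    ok <- is.na(v) | (v == round(v) & v >= 1 & v <= n_categories)
    if (!all(ok)) {
      row <- which(!ok)[1]
      abort(
        paste0("Column `", col, "`, row ", row, ": score ", v[row],
               " is not an integer in 1..", n_categories),
        class = "ordema_validation_error"
      )
    }
  }
  ti <- data[["time_index"]]
  if (anyNA(ti) || any(ti != round(ti)) || any(ti < 0)) {
    row <- which(is.na(ti) | ti != round(ti) | ti < 0)[1]
    abort(paste0("Column `time_index`, row ", row,
                 ": must be a nonnegative integer"),
          class = "ordema_validation_error")
  }
  dup <- duplicated(data[, c("patient_id", "time_index")])
  if (any(dup)) {
    row <- which(dup)[1]
    abort(
      paste0("Duplicated time_index within patient `",
             data$patient_id[row], "` at row ", row),
      class = "ordema_validation_error"
    )
  }
  data
}

#' Keep only fully assessed diary days
#'
#' Complete-case filter: retains the records on which all five predictor
#' items and the outcome were assessed. The number of removed records is
#' reported; an empty result raises a warning.
#'
#' @inheritParams write_ema
#' @return The filtered tibble (row order preserved). Idempotent.
#' @export
filter_complete <- function(data) {
  missing_cols <- setdiff(ema_columns, names(data))
  if (length(missing_cols) > 0) {
    abort(
      paste0("Missing required column(s): ",
             paste(missing_cols, collapse = ", ")),
      class = "ordema_schema_error"
    )
  }
  score_cols <- c(ema_predictors, "self_esteem")
  keep <- stats::complete.cases(data[, score_cols])
  removed <- sum(!keep)
  if (removed > 0) {
    inform(paste0("filter_complete: removed ", removed, " of ", nrow(data),
                  " records with missing scores"))
  }
  out <- tibble::as_tibble(data[keep, , drop = FALSE])
  if (nrow(out) == 0) {
    warn("filter_complete: no complete records remain")
  }
  out
}

#' Summarize an EMA diary dataset
#'
#' Reports the patient count `J`, observation count `N`, per-patient
#' observation counts, and the marginal score frequencies of every item
#' over `1..n_categories`.
#'
#' @inheritParams validate_ema
#' @return An object of class `ema_summary`: a list with elements
#'   `n_patients`, `n_obs`, `per_patient` (tibble of per-patient counts)
#'   and `item_frequencies` (tibble with one row per item and score).
#' @export
ema_summary <- function(data, n_categories = 10) {
  data <- validate_ema(data, n_categories = n_categories)
  per_patient <- data |>
    dplyr::count(.data$patient_id, name = "n_obs")
  score_cols <- c(ema_predictors, "self_esteem")
  freq <- data |>
    dplyr::select(dplyr::all_of(score_cols)) |>
    tidyr::pivot_longer(dplyr::everything(),
                        names_to = "item", values_to = "score") |>
    dplyr::filter(!is.na(.data$score)) |>
    dplyr::count(.data$item, .data$score, name = "n") |>
    tidyr::complete(item = score_cols, score = seq_len(n_categories),
                    fill = list(n = 0L)) |>
    dplyr::arrange(match(.data$item, score_cols), .data$score)
  structure(
    list(
      n_patients = nrow(per_patient),
      n_obs = nrow(data),
      n_categories = n_categories,
      per_patient = per_patient,
      item_frequencies = freq
    ),
    class = "ema_summary"
  )
}

#' @export
print.ema_summary <- function(x, ...) {
  cat("EMA dataset summary\n")
  cat("  patients (J): ", x$n_patients, "\n", sep = "")
  cat("  observations (N): ", x$n_obs, "\n", sep = "")
  cat("  categories (C): ", x$n_categories, "\n", sep = "")
  qs <- quantile(x$per_patient$n_obs, c(0, 0.5, 1))
  cat("  obs per patient: min ", qs[1], ", median ", qs[2],
      ", max ", qs[3], "\n", sep = "")
  invisible(x)
}
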