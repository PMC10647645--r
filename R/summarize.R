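#' Coefficient of variation, in percent
#'
#' `CV = (sigma / mu) * 100`, the dimensionless dispersion of a set of window
#' values relative to its mean. `sigma` defaults to the sample (n - 1)
#' standard deviation; a population-denominator variant is available for
#' sensitivity analysis. When the mean is numerically zero
#' (`|mu| < 1e-12`) the ratio is undefined and `NaN` is returned with a
#' warning, so downstream statistics can drop such cells explicitly.
#'
#' @param values Numeric vector; non-finite entries are dropped. At least two
#'   finite values are required.
#' @param sd_type `"sample"` (n - 1 denominator, default) or `"population"`.
#' @return CV in percent.
#' @examples
#' coefficient_of_variation(c(1, 3)) # 70.71068
#' @export
coefficient_of_variation <- function(values, sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  v <- values[is.finite(values)]
  if (length(v) < 2) {
    abort("Need at least 2 finite values to compute a CV.")
  }
  mu <- mean(v)
  if (abs(mu) < 1e-12) {
    warn("CV undefined: mean is numerically zero; returning NaN.")
    return(NaN)
  }
  s <- sd(v)
  if (sd_type == "population") s <- s * sqrt((length(v) - 1) / length(v))
  s / mu * 100
}

# Non-signalling CV used inside grouped summaries: NaN instead of
# error/warning for degenerate cells (counted via n_windows_used).
cv_quiet <- function(v, sd_type) {
  v <- v[is.finite(v)]
  if (length(v) < 2) {
    return(NaN)
  }
  mu <- mean(v)
  if (abs(mu) < 1e-12) {
    return(NaN)
  }
  s <- sd(v)
  if (sd_type == "population") s <- s * sqrt((length(v) - 1) / length(v))
  s / mu * 100
}

#' Collapse window-resolved metrics into static and dynamic indicators
#'
#' For each epoch (or, with `pool_epochs = TRUE`, each participant x
#' condition, pooling windows across that participant's epochs) and each
#' (network, threshold, metric) cell, computes the static indicator — the
#' mean of the metric over windows — and the dynamic indicator — the
#' coefficient of variation (%) over windows. Non-finite window values
#' (e.g. path length of a fully disconnected window) are excluded and
#' counted via `n_windows_used`.
#'
#' @param window_metrics Long tibble from [graph_metrics()].
#' @param sd_type Standard-deviation denominator for the CV (see
#'   [coefficient_of_variation()]).
#' @param pool_epochs If `FALSE` (default) summaries are per epoch; pass the
#'   result through [aggregate_participants()] to get one value per
#'   participant x condition cell. If `TRUE`, windows are pooled across
#'   epochs before summarizing.
#' @return Tibble keyed by participant, group, condition (and `epoch` unless
#'   pooled), network, threshold, metric, with `static_mean`, `dynamic_cv`,
#'   `n_windows_used`.
#' @export
summarize_windows <- function(window_metrics,
                              sd_type = c("sample", "population"),
                              pool_epochs = FALSE) {
  sd_type <- match.arg(sd_type)
  keys <- c(
    "participant_id", "group", "condition",
    if (!pool_epochs) "epoch", "network", "threshold", "metric"
  )
  missing <- setdiff(c(keys, "value"), names(window_metrics))
  if (length(missing) > 0) {
    abort(paste0("Missing columns: ", paste(missing, collapse = ", ")))
  }
  out <- window_metrics |>
    group_by(across(dplyr::all_of(keys))) |>
    summarise(
      static_mean = if (any(is.finite(.data$value))) {
        mean(.data$value[is.finite(.data$value)])
      } else {
        NaN
      },
      dynamic_cv = cv_quiet(.data$value, sd_type),
      n_windows_used = sum(is.finite(.data$value)),
      .groups = "drop"
    )
  if (any(out$n_windows_used == 0)) {
    warn(paste0(
      sum(out$n_windows_used == 0),
      " summary cell(s) had no finite window values; NaNs emitted."
    ))
  }
  out
}

#' Average epoch-level summaries up to the participant level
#'
#' The group-level models need one value per participant x condition x
#' network x threshold x metric cell; epoch-level static and dynamic
#' indicators are averaged (unweighted) across a participant's epochs within
#' a condition. Non-finite epoch values are dropped.
#'
#' @param summaries Epoch-level tibble from [summarize_windows()].
#' @return Tibble with one row per participant-level cell and columns
#'   `static_mean`, `dynamic_cv`, `n_epochs_used`.
#' @export
aggregate_participants <- function(summaries) {
  keys <- c(
    "participant_id", "group", "condition", "network", "threshold", "metric"
  )
  missing <- setdiff(keys, names(summaries))
  if (length(missing) > 0) {
    abort(paste0("Missing columns: ", paste(missing, collapse = ", ")))
  }
  summaries |>
    group_by(across(dplyr::all_of(keys))) |>
    summarise(
      static_mean = if (any(is.finite(.data$static_mean))) {
        mean(.data$static_mean[is.finite(.data$static_mean)])
      } else {
        NaN
      },
      dynamic_cv = if (any(is.finite(.data$dynamic_cv))) {
        mean(.data$dynamic_cv[is.finite(.data$dynamic_cv)])
      } else {
        NaN
      },
      n_epochs_used = dplyr::n(),
      .groups = "drop"
    )
}
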