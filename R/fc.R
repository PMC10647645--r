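#' Plan sliding windows over an epoch
#'
#' Computes the window/step layout of a sliding-window analysis. Windows are
#' half-open, 0-based sample ranges `[i * step, i * step + window)`; the step
#' is `round(window_samples * (1 - overlap_fraction))` and trailing samples
#' that do not fill a complete window are dropped. With the default task-EEG
#' parameterization — a 25,000-sample (50 s at 500 Hz) epoch, 2000 ms windows
#' and 90% overlap — this yields 241 windows.
#'
#' @param n_samples Samples in the epoch.
#' @param sampling_rate_hz Sampling rate in Hz.
#' @param window_ms Window length in milliseconds (default 2000).
#' @param overlap_fraction Fractional overlap between consecutive windows, in
#'   `[0, 1)` (default 0.9).
#' @return A list with class `"window_plan"`: `window_samples`,
#'   `step_samples`, `n_windows`, `window_ms`, `overlap_fraction`,
#'   `starts` (0-based window start samples).
#' @examples
#' plan_windows(25000, 500, 2000, 0.9)$n_windows # 241
#' @export
plan_windows <- function(n_samples, sampling_rate_hz,
                         window_ms = 2000, overlap_fraction = 0.9) {
  if (overlap_fraction < 0 || overlap_fraction >= 1) {
    abort("`overlap_fraction` must lie in [0, 1).")
  }
  window_samples <- as.integer(round(window_ms / 1000 * sampling_rate_hz))
  if (window_samples < 3) abort("Window must span at least 3 samples.")
  if (window_samples > n_samples) {
    abort(paste0(
      "Window of ", window_samples, " samples exceeds the epoch (",
      n_samples, " samples)."
    ))
  }
  step_samples <- as.integer(round(window_samples * (1 - overlap_fraction)))
  if (step_samples < 1) {
    abort("Step computes to 0 samples; reduce `overlap_fraction`.")
  }
  n_windows <- (n_samples - window_samples) %/% step_samples + 1L
  structure(
    list(
      window_samples = window_samples,
      step_samples = step_samples,
      n_windows = as.integer(n_windows),
      window_ms = window_ms,
      overlap_fraction = overlap_fraction,
      starts = (seq_len(n_windows) - 1L) * step_samples
    ),
    class = "window_plan"
  )
}

#' @export
print.window_plan <- function(x, ...) {
  cat("<window_plan> ", x$n_windows, " windows of ", x$window_samples,
    " samples, step ", x$step_samples, " (", x$window_ms, " ms, ",
    round(100 * x$overlap_fraction), "% overlap)\n",
    sep = ""
  )
  invisible(x)
}

#' Spearman correlation matrix of multichannel data
#'
#' Rank-transforms each ROI's series (midranks on ties) and computes the
#' Pearson correlation of the ranks. ROIs with zero variance inside the
#' window yield `NaN` against every other ROI; the diagonal is always 1.
#'
#' @param x ROI x sample numeric matrix (>= 2 rows, >= 3 columns).
#' @return Symmetric ROI x ROI matrix with unit diagonal, entries in
#'   `[-1, 1]` or `NaN` for degenerate pairs.
#' @export
spearman_matrix <- function(x) {
  if (!is.matrix(x) || nrow(x) < 2 || ncol(x) < 3) {
    abort("`x` must be a matrix with >= 2 ROIs and >= 3 samples.")
  }
  ranks <- apply(x, 1L, fast_rank) # samples x ROI, midranks on ties
  r <- suppressWarnings(cor(ranks))
  r[is.na(r)] <- NaN
  diag(r) <- 1
  dimnames(r) <- list(rownames(x), rownames(x))
  r
}

#' Windowed Spearman FC series for one epoch
#'
#' @param data ROI x sample matrix.
#' @param plan A [plan_windows()] plan built from `ncol(data)`.
#' @return ROI x ROI x window array of Spearman correlation matrices.
#' @export
fc_window_series <- function(data, plan) {
  if (plan$starts[plan$n_windows] + plan$window_samples > ncol(data)) {
    abort("Window plan extends past the end of the epoch.")
  }
  out <- array(
    NA_real_,
    dim = c(nrow(data), nrow(data), plan$n_windows),
    dimnames = list(rownames(data), rownames(data), NULL)
  )
  for (w in seq_len(plan$n_windows)) {
    idx <- (plan$starts[w] + 1L):(plan$starts[w] + plan$window_samples)
    out[, , w] <- spearman_matrix(data[, idx, drop = FALSE])
  }
  out
}

#' Sliding-window functional connectivity for a cohort
#'
#' Maps each epoch of a cohort tibble (as produced by [simulate_cohort()] or
#' [read_cohort()]) to its windowed series of Spearman correlation matrices.
#'
#' @param cohort Tibble with list-column `data` of ROI x sample matrices and
#'   a `sampling_rate_hz` column.
#' @param window_ms,overlap_fraction Passed to [plan_windows()].
#' @return The input tibble with `data` replaced by list-column `fc`
#'   (ROI x ROI x window arrays) and columns `n_windows`; the window plan is
#'   attached as attribute `"plan"`.
#' @export
compute_fc <- function(cohort, window_ms = 2000, overlap_fraction = 0.9) {
  stopifnot(is.data.frame(cohort), "data" %in% names(cohort))
  fs <- unique(cohort$sampling_rate_hz)
  if (length(fs) != 1) abort("All epochs must share one sampling rate.")
  n_samp <- unique(vapply(cohort$data, ncol, integer(1)))
  if (length(n_samp) != 1) abort("All epochs must have the same sample count.")
  plan <- plan_windows(n_samp, fs, window_ms, overlap_fraction)
  out <- cohort
  out$fc <- purrr::map(cohort$data, function(x) {
    fc <- cpp_fc_series(x, plan$starts, plan$window_samples)
    dimnames(fc) <- list(rownames(x), rownames(x), NULL)
    fc
  })
  out$n_windows <- plan$n_windows
  out$data <- NULL
  attr(out, "plan") <- plan
  out
}

#' Binarize a correlation matrix at a threshold
#'
#' An (undirected, unweighted) edge joins ROIs i and j iff their correlation
#' strictly exceeds the threshold. Negative and `NaN` correlations never
#' produce edges; a value exactly equal to the threshold is excluded; the
#' diagonal is zero.
#'
#' @param fc Symmetric correlation matrix.
#' @param threshold Correlation cutoff in `(0, 1)`.
#' @return 0/1 adjacency matrix of the same dimension.
#' @export
binarize <- function(fc, threshold) {
  if (threshold <= 0 || threshold >= 1) abort("`threshold` must lie in (0, 1).")
  adj <- (!is.na(fc) & fc > threshold) * 1
  diag(adj) <- 0
  adj
}

#' Restrict a matrix to one network's ROIs
#'
#' Returns the principal submatrix (correlation or adjacency) over the ROIs
#' of the named network, in the network's ROI order; `"brain"` returns the
#' full matrix. Because both Spearman correlation and thresholding act
#' pairwise, restricting commutes with binarization.
#'
#' @param m ROI x ROI matrix with ROI dimnames.
#' @param map A [network_map()].
#' @param network Network name or `"brain"`.
#' @return The restricted matrix.
#' @export
extract_network_subgraph <- function(m, map, network) {
  if (identical(network, "brain")) {
    return(m)
  }
  rois <- network_rois(map, network)
  missing <- setdiff(rois, rownames(m))
  if (length(missing) > 0) {
    abort(paste0("ROI label(s) not present: ", paste(missing, collapse = ", ")))
  }
  m[rois, rois, drop = FALSE]
}
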