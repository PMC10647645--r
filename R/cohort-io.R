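#' Read and write epoch matrices
#'
#' Each epoch is stored as a delimited text matrix (tab-separated, one column
#' per ROI with a header row of ROI labels, one row per sample) plus a JSON
#' sidecar `<file>.json` holding `participant_id`, `group`, `condition`,
#' `epoch` and `sampling_rate_hz`. The in-memory orientation is ROI x sample.
#'
#' @param data ROI x sample matrix with ROI rownames.
#' @param path Path of the `.tsv` matrix file.
#' @param meta Named list with `participant_id`, `group`, `condition`,
#'   `epoch`, `sampling_rate_hz`.
#' @return `write_epoch()` returns `path` invisibly; `read_epoch()` returns
#'   a one-row tibble in the cohort layout (metadata columns + `data`
#'   list-column).
#' @export
write_epoch <- function(data, path, meta) {
  stopifnot(is.matrix(data), !is.null(rownames(data)))
  need <- c("participant_id", "group", "condition", "epoch", "sampling_rate_hz")
  missing <- setdiff(need, names(meta))
  if (length(missing) > 0) {
    abort(paste0("Sidecar metadata missing: ", paste(missing, collapse = ", ")))
  }
  df <- as.data.frame(t(data))
  readr::write_tsv(df, path, progress = FALSE)
  jsonlite::write_json(meta[need], paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_epoch
#' @export
read_epoch <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) abort(paste0("Missing sidecar: ", sidecar))
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  for (f in c("participant_id", "group", "condition", "epoch", "sampling_rate_hz")) {
    if (is.null(meta[[f]])) {
      abort(paste0("Sidecar ", sidecar, " lacks field `", f, "`."))
    }
  }
  df <- readr::read_tsv(path,
    progress = FALSE, show_col_types = FALSE,
    col_types = readr::cols(.default = readr::col_double())
  )
  m <- t(as.matrix(df))
  if (any(!is.finite(m))) {
    abort(paste0("Non-finite values in epoch matrix ", path, "."))
  }
  tibble(
    participant_id = as.character(meta$participant_id),
    group = as.character(meta$group),
    condition = as.character(meta$condition),
    epoch = as.integer(meta$epoch),
    sampling_rate_hz = as.numeric(meta$sampling_rate_hz),
    data = list(m)
  )
}

#' Write a cohort to disk
#'
#' Writes one matrix + sidecar pair per epoch and a `manifest.csv` indexing
#' them.
#'
#' @param cohort Cohort tibble (from [simulate_cohort()]).
#' @param dir Output directory (created if needed).
#' @return The manifest tibble, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- sprintf(
    "%s_%s_e%02d.tsv",
    cohort$participant_id, cohort$condition, cohort$epoch
  )
  for (i in seq_len(nrow(cohort))) {
    write_epoch(
      cohort$data[[i]], file.path(dir, files[i]),
      meta = list(
        participant_id = cohort$participant_id[i],
        group = cohort$group[i],
        condition = cohort$condition[i],
        epoch = cohort$epoch[i],
        sampling_rate_hz = cohort$sampling_rate_hz[i]
      )
    )
  }
  manifest <- dplyr::bind_cols(
    cohort[, c("participant_id", "group", "condition", "epoch", "sampling_rate_hz")],
    tibble(file = files)
  )
  readr::write_csv(manifest, file.path(dir, "manifest.csv"), progress = FALSE)
  invisible(manifest)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  manifest_path <- file.path(dir, "manifest.csv")
  if (!file.exists(manifest_path)) {
    abort(paste0("No manifest.csv in ", dir))
  }
  manifest <- readr::read_csv(manifest_path,
    progress = FALSE, show_col_types = FALSE
  )
  rows <- purrr::map(file.path(dir, manifest$file), read_epoch)
  dplyr::bind_rows(rows)
}
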