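#' @useDynLib dynfc, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom rlang %||% .data abort warn inform
#' @importFrom dplyr mutate filter select arrange group_by ungroup summarise
#'   across left_join bind_rows distinct n pull rename relocate
#' @importFrom tibble tibble as_tibble
#' @importFrom stats cor sd rexp rnorm p.adjust anova lm setNames
NULL

# Canonical metric names, in the order they are reported.
metric_names <- function() {
  c(
    "clustering", "transitivity",
    "efficiency", "char_path_length",
    "degree", "betweenness", "eccentricity", "diameter",
    "assortativity", "kcore"
  )
}

#' Default binarization threshold grid
#'
#' The sweep used throughout: correlations from 0.1 to 0.6 in steps of 0.1.
#'
#' @return Numeric vector of thresholds.
#' @export
default_thresholds <- function() seq(0.1, 0.6, by = 0.1)

check_thresholds <- function(thresholds) {
  if (length(thresholds) == 0 || any(!is.finite(thresholds))) {
    abort("`thresholds` must be a non-empty finite numeric vector.")
  }
  if (any(thresholds <= 0) || any(thresholds >= 1)) {
    abort("`thresholds` must lie strictly inside (0, 1).")
  }
  if (is.unsorted(thresholds, strictly = TRUE)) {
    abort("`thresholds` must be strictly increasing.")
  }
  as.numeric(thresholds)
}

# Deterministic per-epoch substream seed derived from the master seed and the
# epoch coordinates, kept below 2^31 so it is a valid R integer seed.
derive_seed <- function(master_seed, participant_index, condition_index, epoch_index) {
  m <- 2147483629
  s <- (as.numeric(master_seed) %% m +
    1000003 * participant_index +
    7919 * condition_index +
    104729 * epoch_index) %% m
  as.integer(s)
}

# rank() with midranks on ties, but the cheap double-order path when the
# window is tie-free (the typical case for continuous signals).
fast_rank <- function(v) {
  if (anyDuplicated(v)) rank(v) else order(order(v))
}

is_square_symmetric <- function(x, tol = 1e-10) {
  is.matrix(x) && nrow(x) == ncol(x) &&
    isTRUE(all.equal(x, t(x), tolerance = tol, check.attributes = FALSE))
}

check_adjacency <- function(adjacency) {
  if (!is.matrix(adjacency) || nrow(adjacency) != ncol(adjacency)) {
    abort("`adjacency` must be a square matrix.")
  }
  if (!all(adjacency %in% c(0, 1))) {
    abort("`adjacency` must be a 0/1 matrix.")
  }
  if (any(diag(adjacency) != 0)) {
    abort("`adjacency` must have a zero diagonal (no self-loops).")
  }
  if (!isTRUE(all.equal(adjacency, t(adjacency), check.attributes = FALSE))) {
    abort("`adjacency` must be symmetric (undirected graph).")
  }
  storage.mode(adjacency) <- "double"
  adjacency
}
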