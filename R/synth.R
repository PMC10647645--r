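#' Latent connectivity-state parameters
#'
#' Parameters of the generative model for one group x condition cell: ROI
#' activity is drawn from a small repertoire of latent connectivity states.
#' Each state is a zero-mean Gaussian whose correlation matrix has elevated
#' within-network correlation and a lower cross-network baseline; the active
#' state follows a continuous-time-style Markov chain with exponential dwell
#' times. Slower switching (smaller `switch_rate_scale`) yields fewer state
#' transitions per epoch and therefore lower window-to-window variability of
#' functional connectivity, while leaving time-averaged (static) connectivity
#' essentially unchanged — the dissociation the static/dynamic analysis is
#' designed to detect.
#'
#' @param n_states Number of latent connectivity states (default 4).
#' @param within_network_rho Target within-network correlation, in `[0, 1)`.
#'   States modulate this target per network so that states are
#'   distinguishable (see [build_state_covariances()]).
#' @param between_network_rho Baseline cross-network correlation; must satisfy
#'   `0 <= between_network_rho <= within_network_rho < 1`.
#' @param mean_dwell_s Mean dwell time of a state, in seconds, at
#'   `switch_rate_scale = 1`.
#' @param switch_rate_scale Multiplier on the state-switching rate. The
#'   realized mean dwell is `mean_dwell_s / switch_rate_scale`, so values
#'   below 1 slow the dynamics (e.g. 0.5 halves the switching rate).
#' @param noise_sd Standard deviation of additive white sensor/source noise.
#'   Noise attenuates observed correlations by `1 / (1 + noise_sd^2)`.
#'
#' @return A list with class `"state_params"`.
#' @export
state_params <- function(n_states = 4,
                         within_network_rho = 0.7,
                         between_network_rho = 0.1,
                         mean_dwell_s = 5,
                         switch_rate_scale = 1,
                         noise_sd = 0.25) {
  if (n_states < 1) abort("`n_states` must be >= 1.")
  if (within_network_rho < 0 || within_network_rho >= 1) {
    abort("`within_network_rho` must lie in [0, 1).")
  }
  if (between_network_rho < 0 || between_network_rho > within_network_rho) {
    abort("Need 0 <= between_network_rho <= within_network_rho < 1.")
  }
  if (mean_dwell_s <= 0) abort("`mean_dwell_s` must be positive.")
  if (switch_rate_scale <= 0) abort("`switch_rate_scale` must be positive.")
  if (noise_sd < 0) abort("`noise_sd` must be non-negative.")
  structure(
    list(
      n_states = as.integer(n_states),
      within_network_rho = within_network_rho,
      between_network_rho = between_network_rho,
      mean_dwell_s = mean_dwell_s,
      switch_rate_scale = switch_rate_scale,
      noise_sd = noise_sd
    ),
    class = "state_params"
  )
}

#' Synthetic cohort specification
#'
#' Describes a full two-group, two-condition cohort of epoched ROI time
#' series. Defaults mirror a task-EEG study design: 50 s epochs sampled at
#' 500 Hz (25,000 samples per ROI per epoch), two groups of 20 participants,
#' two attentional conditions, and a whole-cortex 68-ROI parcellation.
#'
#' @param n_per_group Participants per group (>= 2, default 20).
#' @param groups Two group labels (default `c("SZ", "HC")`).
#' @param conditions Condition labels (default `c("MW", "OT")`).
#' @param epochs_per_condition Epochs per participant per condition
#'   (default 10, i.e. 20 epochs per participant across both conditions).
#' @param epoch_duration_s Epoch length in seconds (default 50).
#' @param sampling_rate_hz Sampling rate in Hz (default 500);
#'   `epoch_duration_s * sampling_rate_hz` must be a whole number of samples.
#' @param network_map A [network_map()] assigning every ROI to exactly one
#'   network; defaults to the shipped 68-ROI mapping ([dk_network_map()]).
#' @param state_params Either a single [state_params()] used for every
#'   group x condition cell, or a named list keyed `"<group>.<condition>"`
#'   (missing cells fall back to a `"<group>"` entry, then to `"default"`).
#' @param seed Master RNG seed (integer). Every epoch draws from its own
#'   substream derived from `(seed, participant, condition, epoch)`, so the
#'   cohort is a pure function of this specification.
#'
#' @return A list with class `"cohort_spec"`.
#' @examples
#' spec <- cohort_spec(
#'   n_per_group = 2, epochs_per_condition = 1, epoch_duration_s = 2,
#'   network_map = split_network_map(8, c("DMN", "VIS")), seed = 1
#' )
#' cohort <- simulate_cohort(spec)
#' @export
cohort_spec <- function(n_per_group = 20,
                        groups = c("SZ", "HC"),
                        conditions = c("MW", "OT"),
                        epochs_per_condition = 10,
                        epoch_duration_s = 50,
                        sampling_rate_hz = 500,
                        network_map = dk_network_map(),
                        state_params = dynfc::state_params(),
                        seed = 1L) {
  if (n_per_group < 2) abort("`n_per_group` must be >= 2.")
  if (length(groups) < 1 || anyDuplicated(groups)) abort("`groups` must be distinct labels.")
  if (length(conditions) < 1 || anyDuplicated(conditions)) {
    abort("`conditions` must be distinct labels.")
  }
  if (epochs_per_condition < 1) abort("`epochs_per_condition` must be >= 1.")
  n_samples <- epoch_duration_s * sampling_rate_hz
  if (abs(n_samples - round(n_samples)) > 1e-9) {
    abort("`epoch_duration_s * sampling_rate_hz` must be an integer sample count.")
  }
  map <- validate_network_map(unclass(network_map))
  if (inherits(state_params, "state_params")) {
    state_params <- list(default = state_params)
  }
  if (!all(vapply(state_params, inherits, logical(1), "state_params"))) {
    abort("`state_params` must be state_params objects.")
  }
  structure(
    list(
      n_per_group = as.integer(n_per_group),
      groups = as.character(groups),
      conditions = as.character(conditions),
      epochs_per_condition = as.integer(epochs_per_condition),
      epoch_duration_s = epoch_duration_s,
      sampling_rate_hz = sampling_rate_hz,
      n_samples = as.integer(round(n_samples)),
      network_map = map,
      state_params = state_params,
      seed = as.integer(seed)
    ),
    class = "cohort_spec"
  )
}

# Resolve the state_params entry for one group x condition cell.
cell_params <- function(spec, group, condition) {
  sp <- spec$state_params
  key <- paste(group, condition, sep = ".")
  sp[[key]] %||% sp[[group]] %||% sp[["default"]] %||%
    abort(paste0("No state_params for cell ", key, " and no default."))
}

#' Build the per-state ROI correlation matrices
#'
#' Constructs `n_states` symmetric positive semi-definite correlation
#' matrices with unit diagonal. Each state carries the same correlation
#' magnitudes — `within_network_rho` inside a community,
#' `between_network_rho` across communities — but a reorganized community
#' structure: state s rotates the ROI-to-community assignment of the network
#' map by `round((s - 1) * n_roi / n_states)` positions. State 1 is exactly
#' the declared network map; a single state therefore reproduces the target
#' pattern verbatim. Because all states share the same block sizes and
#' correlation levels, their graphs are statistically equivalent in density
#' and metric level — states differ in *which* ROI pairs cohere, not in how
#' strongly. A connectivity repertoire of this kind dissociates the static
#' mean (level, identical across states) from the dynamic CV (reconfiguration
#' across windows). Any matrix that is not positive semi-definite is shrunk
#' toward the identity (`0.95 * S` off-diagonal, preserving the unit
#' diagonal) until its smallest eigenvalue is non-negative.
#'
#' @param params A [state_params()].
#' @param network_map A [network_map()]; its ROI order defines row order.
#' @param max_shrink_iter Maximum shrinkage iterations before giving up.
#' @return A list of `n_states` correlation matrices (ROI x ROI, dimnames set
#'   to ROI labels).
#' @export
build_state_covariances <- function(params, network_map, max_shrink_iter = 40L) {
  rois <- roi_labels(network_map)
  n_roi <- length(rois)
  n_states <- params$n_states
  membership <- rep(seq_along(network_map), lengths(network_map))
  out <- vector("list", n_states)
  for (s in seq_len(n_states)) {
    offset <- round((s - 1) * n_roi / n_states)
    member_s <- membership[((seq_len(n_roi) - 1 + offset) %% n_roi) + 1]
    same <- outer(member_s, member_s, "==")
    sigma <- matrix(params$between_network_rho, n_roi, n_roi)
    sigma[same] <- params$within_network_rho
    diag(sigma) <- 1
    iter <- 0L
    while (min(eigen(sigma, symmetric = TRUE, only.values = TRUE)$values) < -1e-10) {
      if (iter >= max_shrink_iter) {
        abort(paste0("State ", s, ": correlation matrix not PSD after ",
                     max_shrink_iter, " shrinkage iterations."))
      }
      sigma <- 0.95 * sigma
      diag(sigma) <- 1
      iter <- iter + 1L
    }
    dimnames(sigma) <- list(rois, rois)
    out[[s]] <- sigma
  }
  out
}

# Sample the latent state sequence at sample resolution: exponential dwell
# times of mean mean_dwell_s / switch_rate_scale; successive states uniform
# over the remaining states.
sample_state_sequence <- function(n_samples, sampling_rate_hz, params) {
  if (params$n_states == 1) {
    return(rep.int(1L, n_samples))
  }
  dwell_samples <- params$mean_dwell_s / params$switch_rate_scale * sampling_rate_hz
  states <- integer(n_samples)
  t <- 0L
  current <- sample.int(params$n_states, 1)
  while (t < n_samples) {
    len <- max(1L, as.integer(round(rexp(1, rate = 1 / dwell_samples))))
    len <- min(len, n_samples - t)
    states[(t + 1L):(t + len)] <- current
    t <- t + len
    others <- setdiff(seq_len(params$n_states), current)
    current <- if (length(others) == 1) others else sample(others, 1)
  }
  states
}

#' Simulate one epoch of ROI time series
#'
#' Draws an ROI x sample matrix from the latent-state model: a state sequence
#' at sample resolution, Gaussian emissions from the active state's
#' correlation matrix, plus additive white noise. Deterministic given the
#' spec's master seed and the epoch coordinates.
#'
#' @param spec A [cohort_spec()].
#' @param participant_index 1-based participant index within the cohort.
#' @param group,condition Labels from the spec.
#' @param epoch_index 1-based epoch index within the condition.
#' @param return_states If `TRUE`, attach the latent state sequence as
#'   attribute `"states"` (used for calibration checks).
#' @return ROI x sample numeric matrix; rownames are ROI labels.
#' @export
simulate_epoch <- function(spec, participant_index, group, condition,
                           epoch_index = 1L, return_states = FALSE) {
  params <- cell_params(spec, group, condition)
  chols <- lapply(build_state_covariances(params, spec$network_map), chol)
  simulate_epoch_impl(
    spec, chols, params, participant_index, condition, epoch_index,
    return_states = return_states
  )
}

simulate_epoch_impl <- function(spec, chols, params, participant_index,
                                condition, epoch_index,
                                return_states = FALSE) {
  rois <- roi_labels(spec$network_map)
  n_roi <- length(rois)
  n <- spec$n_samples
  cond_index <- match(condition, spec$conditions)
  if (is.na(cond_index)) abort(paste0("Unknown condition: ", condition))
  seed <- derive_seed(spec$seed, participant_index, cond_index, epoch_index)
  x <- withr::with_seed(seed, {
    states <- sample_state_sequence(n, spec$sampling_rate_hz, params)
    z <- matrix(rnorm(n_roi * n), nrow = n_roi)
    out <- matrix(0, n_roi, n)
    for (s in unique(states)) {
      idx <- which(states == s)
      out[, idx] <- t(chols[[s]]) %*% z[, idx, drop = FALSE]
    }
    if (params$noise_sd > 0) {
      out <- out + params$noise_sd * matrix(rnorm(n_roi * n), nrow = n_roi)
    }
    attr(out, "states") <- states
    out
  })
  states <- attr(x, "states")
  attr(x, "states") <- NULL
  rownames(x) <- rois
  if (return_states) attr(x, "states") <- states
  x
}

#' Simulate a full synthetic cohort
#'
#' Generates every epoch of the cohort described by a [cohort_spec()] and
#' returns them in a tibble manifest with one row per epoch, the ROI x sample
#' matrix held in the `data` list-column. The result is a pure function of
#' the spec (including its seed) and pipes directly into [compute_fc()].
#'
#' @param spec A [cohort_spec()].
#' @return A tibble with columns `participant_id`, `group`, `condition`,
#'   `epoch`, `sampling_rate_hz` and list-column `data`.
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  grid <- tidyr::expand_grid(
    group = spec$groups,
    member = seq_len(spec$n_per_group),
    condition = spec$conditions,
    epoch = seq_len(spec$epochs_per_condition)
  )
  # Participant indices run across groups: group g, member m ->
  # (g - 1) * n_per_group + m, giving globally unique ids.
  grid$participant_index <-
    (match(grid$group, spec$groups) - 1L) * spec$n_per_group + grid$member
  grid$participant_id <- sprintf("P%03d", grid$participant_index)
  if (anyDuplicated(unique(grid[, c("participant_id", "group")])$participant_id)) {
    abort("Duplicate participant ids across groups.")
  }
  # State covariances (and their Cholesky factors) are shared within a
  # group x condition cell; build each once.
  cells <- unique(grid[, c("group", "condition")])
  chol_cache <- list()
  param_cache <- list()
  for (i in seq_len(nrow(cells))) {
    key <- paste(cells$group[i], cells$condition[i], sep = ".")
    param_cache[[key]] <- cell_params(spec, cells$group[i], cells$condition[i])
    chol_cache[[key]] <- lapply(
      build_state_covariances(param_cache[[key]], spec$network_map), chol
    )
  }
  data <- purrr::pmap(
    list(grid$participant_index, grid$group, grid$condition, grid$epoch),
    function(p, g, c, e) {
      key <- paste(g, c, sep = ".")
      simulate_epoch_impl(spec, chol_cache[[key]], param_cache[[key]], p, c, e)
    }
  )
  tibble(
    participant_id = grid$participant_id,
    group = grid$group,
    condition = grid$condition,
    epoch = grid$epoch,
    sampling_rate_hz = spec$sampling_rate_hz,
    data = data
  )
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("<cohort_spec> ", length(x$groups), " groups x ", x$n_per_group,
    " participants, ", length(x$conditions), " conditions x ",
    x$epochs_per_condition, " epochs\n",
    "  epoch: ", x$epoch_duration_s, " s @ ", x$sampling_rate_hz, " Hz = ",
    x$n_samples, " samples, ", length(roi_labels(x$network_map)),
    " ROIs, seed ", x$seed, "\n",
    sep = ""
  )
  invisible(x)
}
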