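# Shared scaled-down study conditions for the Monte-Carlo checks: two groups
# of 10 participants, 8 ROIs in two networks, 5 s epochs at 500 Hz, 250 ms
# windows at 80% overlap, default six-threshold sweep, brain-network global
# efficiency as the probe metric.
#
# The latent states are iso-density reconfigurations (same correlation
# magnitudes, rotated community structure), so every state has the same
# expected metric level; window-to-window variability comes from windows that
# straddle state transitions. The dwell time (2.5 s) keeps several dwells per
# epoch while windows (0.25 s) are much shorter than a dwell — the regime in
# which halving the switching rate visibly reduces the number of
# reconfigurations an epoch samples, and with it the dynamic CV, while the
# static mean is nearly untouched. Effect cohorts use 6 epochs per
# participant (stabilizing the participant-level CV the way the reference
# design's many segments do); null cohorts, which only probe test
# calibration, use 2.

mc_network_map <- function() split_network_map(8, c("DMN", "VIS"))

mc_state_params <- function(switch_rate_scale = 1) {
  state_params(
    n_states = 3, within_network_rho = 0.7, between_network_rho = 0.1,
    mean_dwell_s = 2.5, switch_rate_scale = switch_rate_scale, noise_sd = 0.25
  )
}

mc_cohort_spec <- function(seed, n_per_group = 10, epochs_per_condition = 2,
                           sz_switch_rate_scale = 1) {
  cohort_spec(
    n_per_group = n_per_group, groups = c("SZ", "HC"), conditions = "OT",
    epochs_per_condition = epochs_per_condition,
    epoch_duration_s = 5, sampling_rate_hz = 500,
    network_map = mc_network_map(),
    state_params = list(
      SZ = mc_state_params(sz_switch_rate_scale),
      HC = mc_state_params(1)
    ),
    seed = seed
  )
}

# Simulation -> FC -> metrics -> participant summaries for one cohort.
mc_participant_summaries <- function(spec) {
  simulate_cohort(spec) |>
    compute_fc(window_ms = 250, overlap_fraction = 0.8) |>
    graph_metrics(
      map = spec$network_map, networks = "brain", metrics = "efficiency"
    ) |>
    summarize_windows() |>
    aggregate_participants()
}
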