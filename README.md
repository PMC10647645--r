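# dynfc

Static and dynamic graph-theoretic analysis of EEG functional connectivity.

`dynfc` implements a complete group-comparison pipeline for task-based EEG
that has been parcellated into region-of-interest (ROI) time series: it is
aimed at researchers who want to ask whether two groups (for example,
patients with schizophrenia and healthy controls) differ in the *temporal
variability* of their brain-network organization, not only in its average.

## The method

Starting from an ROI x sample matrix per epoch (e.g. 50 s at 500 Hz = 25,000
samples), the pipeline:

1. slides a window (default 2000 ms, 90% overlap) along each epoch and
   computes the **Spearman correlation matrix** of the ROI series in every
   window — with the defaults, 241 matrices per 50 s epoch;
2. **binarizes** each matrix across a threshold sweep
   tau in {0.1, ..., 0.6}; an undirected, unweighted edge joins two ROIs iff
   r > tau, and negative correlations are excluded;
3. computes **ten graph measures** on every binary network and on each named
   subnetwork (DMN, DAN, SAN, VIS, and "brain" = all ROIs): segregation
   (clustering coefficient, transitivity), integration (global efficiency,
   characteristic path length), centrality (degree, betweenness,
   eccentricity, diameter) and resilience (degree assortativity, k-core
   coreness);
4. collapses the window-resolved metrics into a **static** indicator (the
   mean over windows) and a **dynamic** indicator (the coefficient of
   variation, CV = sigma/mu x 100) per participant, condition, network,
   threshold and metric;
5. compares groups with a **mixed-effects ANOVA** (group, threshold and
   their interaction fixed; participant random; Type III F tests with
   Satterthwaite df), or a participant-level **permutation test**, with
   Benjamini-Hochberg FDR control and per-threshold estimated-marginal-mean
   post hocs — summarized in a "diamond" significance matrix.

Because clinical EEG data cannot be redistributed, the package ships a
first-class **synthetic cohort generator**: ROI activity is drawn from a
small repertoire of latent connectivity states (iso-density community
reconfigurations) visited by a Markov chain with exponential dwell times.
Slowing the state-switching rate of one group lowers its dynamic CV while
leaving static means essentially unchanged — the dissociation the analysis
is designed to detect — so every stage of the pipeline is testable end to
end.

## Worked example

```r
library(dynfc)

nm <- split_network_map(8, c("DMN", "VIS"))
spec <- cohort_spec(
  n_per_group = 10, groups = c("SZ", "HC"), conditions = "OT",
  epochs_per_condition = 6, epoch_duration_s = 5, sampling_rate_hz = 500,
  network_map = nm,
  state_params = list(
    SZ = state_params(n_states = 3, mean_dwell_s = 2.5,
                      switch_rate_scale = 0.5, noise_sd = 0.25),
    HC = state_params(n_states = 3, mean_dwell_s = 2.5,
                      switch_rate_scale = 1, noise_sd = 0.25)
  ),
  seed = 42
)

summaries <- simulate_cohort(spec) |>
  compute_fc(window_ms = 250, overlap_fraction = 0.8) |>
  graph_metrics(map = nm, networks = "brain", metrics = "efficiency") |>
  summarize_windows() |>
  aggregate_participants()

res <- test_group_differences(summaries)
tidy(res)
```

```
# A tibble: 6 × 10
  condition network metric     summary_type effect            statistic df_num df_den   p_value p_adjusted
  <chr>     <chr>   <chr>      <chr>        <chr>                 <dbl>  <int>  <dbl>     <dbl>      <dbl>
1 OT        brain   efficiency static       group                 0.135      1   18.0 7.18e-  1  7.18e-  1
2 OT        brain   efficiency static       threshold         10961.         5   90.0 1.09e-123  3.26e-123
3 OT        brain   efficiency static       group x threshold     3.67       5   90.0 4.56e-  3  6.84e-  3
4 OT        brain   efficiency dynamic      group                11.5        1   18.0 3.21e-  3  3.21e-  3
5 OT        brain   efficiency dynamic      threshold           893.         5   90.0 4.77e- 75  1.43e- 74
6 OT        brain   efficiency dynamic      group x threshold     5.74       5   90.0 1.22e-  4  1.82e-  4
```

The simulated patient group (switching rate halved) shows a clear group
effect on the *dynamic* CV of global efficiency (F = 11.5, adjusted
p = 0.0032) and no group main effect on the *static* mean (p = 0.72) —
temporal reorganization differs while average connectivity does not.
`significance_matrix(res)` reduces the post hoc contrasts to the diamond
rule (a cell is marked when any threshold survives FDR):

```
# A tibble: 2 × 6
  condition network metric     summary_type n_sig_thresholds significant
  <chr>     <chr>   <chr>      <chr>                   <int> <lgl>
1 OT        brain   efficiency dynamic                     4 TRUE
2 OT        brain   efficiency static                      0 FALSE
```

`autoplot(res)` draws the diamond grid.

A full multi-network run is one call:

```r
res <- run_pipeline(pipeline_config(spec), out = "results/run1")
```

which writes every stage's table (window metrics, epoch and participant
summaries, tests, post hocs, significance matrix) as CSV plus a
`provenance.json` with the config hash and seed.

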