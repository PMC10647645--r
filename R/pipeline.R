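#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end analysis. The defaults reproduce
#' the reference task-EEG parameterization: 2000 ms windows with 90% overlap,
#' thresholds 0.1-0.6 in steps of 0.1, CV in percent with a sample-SD
#' denominator, mixed-model inference at alpha 0.05 with BH FDR.
#'
#' @param cohort A [cohort_spec()] to simulate, or a directory of epochs
#'   written by [write_cohort()].
#' @param window_ms,overlap_fraction Sliding-window layout.
#' @param thresholds Binarization sweep.
#' @param networks Networks to analyse (default: all named networks plus
#'   `"brain"`).
#' @param metrics Graph metrics to compute.
#' @param sd_type,pool_epochs Summary options (see [summarize_windows()]).
#' @param engine,alpha,n_perm,fdr_family,posthoc_family,singular_action
#'   Inference options (see [test_group_differences()]).
#' @param seed Master seed for the inference stage (simulation randomness is
#'   governed by the cohort spec's own seed).
#' @return A list with class `"pipeline_config"`.
#' @export
pipeline_config <- function(cohort,
                            window_ms = 2000,
                            overlap_fraction = 0.9,
                            thresholds = default_thresholds(),
                            networks = NULL,
                            metrics = metric_names(),
                            sd_type = "sample",
                            pool_epochs = FALSE,
                            engine = "mixed",
                            alpha = 0.05,
                            n_perm = 999,
                            fdr_family = "stratum",
                            posthoc_family = "within_metric",
                            singular_action = "warn",
                            seed = 1L) {
  structure(
    list(
      cohort = cohort,
      window_ms = window_ms,
      overlap_fraction = overlap_fraction,
      thresholds = check_thresholds(thresholds),
      networks = networks,
      metrics = match.arg(metrics, metric_names(), several.ok = TRUE),
      sd_type = sd_type,
      pool_epochs = pool_epochs,
      engine = engine,
      alpha = alpha,
      n_perm = n_perm,
      fdr_family = fdr_family,
      posthoc_family = posthoc_family,
      singular_action = singular_action,
      seed = as.integer(seed)
    ),
    class = "pipeline_config"
  )
}

#' Serialize a pipeline configuration to YAML
#'
#' Round-trips losslessly through [read_pipeline_config()]. A cohort given as
#' a [cohort_spec()] is expanded field by field; `state_params` entries are
#' stored as plain lists.
#'
#' @param config A [pipeline_config()].
#' @param path YAML file path.
#' @return `path`, invisibly.
#' @export
write_pipeline_config <- function(config, path) {
  x <- unclass(config)
  if (inherits(x$cohort, "cohort_spec")) {
    cs <- unclass(x$cohort)
    cs$network_map <- lapply(unclass(cs$network_map), as.list)
    cs$state_params <- lapply(cs$state_params, unclass)
    x$cohort <- list(spec = cs)
  } else {
    x$cohort <- list(dir = x$cohort)
  }
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  if (!is.null(x$cohort$spec)) {
    cs <- x$cohort$spec
    cohort <- cohort_spec(
      n_per_group = cs$n_per_group,
      groups = unlist(cs$groups),
      conditions = unlist(cs$conditions),
      epochs_per_condition = cs$epochs_per_condition,
      epoch_duration_s = cs$epoch_duration_s,
      sampling_rate_hz = cs$sampling_rate_hz,
      network_map = validate_network_map(
        lapply(cs$network_map, unlist)
      ),
      state_params = lapply(cs$state_params, function(p) {
        do.call(state_params, p)
      }),
      seed = cs$seed
    )
  } else {
    cohort <- x$cohort$dir
  }
  pipeline_config(
    cohort = cohort,
    window_ms = x$window_ms,
    overlap_fraction = x$overlap_fraction,
    thresholds = unlist(x$thresholds),
    networks = if (is.null(x$networks)) NULL else unlist(x$networks),
    metrics = unlist(x$metrics),
    sd_type = x$sd_type,
    pool_epochs = x$pool_epochs,
    engine = x$engine,
    alpha = x$alpha,
    n_perm = x$n_perm,
    fdr_family = x$fdr_family,
    posthoc_family = x$posthoc_family,
    singular_action = x$singular_action,
    seed = x$seed
  )
}

#' Run the full analysis pipeline
#'
#' Simulate (or ingest) a cohort, compute sliding-window Spearman FC,
#' binarize across the threshold sweep, extract graph metrics per network,
#' collapse windows into static/dynamic indicators, and compare groups. When
#' `out` is given, every stage's table is written as CSV together with a
#' `provenance.json` (config hash, seed, package version); partial outputs
#' are retained if a later stage fails.
#'
#' @param config A [pipeline_config()].
#' @param out Optional output directory.
#' @param network_map Required when `config$cohort` is a directory; ignored
#'   (taken from the spec) when simulating.
#' @return List with `cohort` (manifest columns only), `window_metrics`,
#'   `epoch_summaries`, `participant_summaries`, `stats`,
#'   `significance`, and `plan`.
#' @export
run_pipeline <- function(config, out = NULL, network_map = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(out)) dir.create(out, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("Pipeline stage `", name, "` failed: ", conditionMessage(e)))
    })
  }
  if (inherits(config$cohort, "cohort_spec")) {
    map <- config$cohort$network_map
    cohort <- stage("simulate", simulate_cohort(config$cohort))
  } else {
    if (is.null(network_map)) {
      abort("`network_map` is required when reading epochs from a directory.")
    }
    map <- network_map
    cohort <- stage("ingest", read_cohort(config$cohort))
  }
  networks <- config$networks %||% c(network_names(map), "brain")
  fc_tbl <- stage(
    "fc", compute_fc(cohort, config$window_ms, config$overlap_fraction)
  )
  plan <- attr(fc_tbl, "plan")
  wm <- stage("graph", graph_metrics(
    fc_tbl, map,
    thresholds = config$thresholds,
    networks = networks, metrics = config$metrics
  ))
  es <- stage("summarize", summarize_windows(
    wm,
    sd_type = config$sd_type, pool_epochs = config$pool_epochs
  ))
  ps <- if (config$pool_epochs) es else stage("aggregate", aggregate_participants(es))
  writer <- function(tbl, name) {
    if (!is.null(out)) {
      readr::write_csv(tbl, file.path(out, name), progress = FALSE)
    }
  }
  manifest <- cohort[, setdiff(names(cohort), c("data", "fc"))]
  writer(manifest, "cohort_manifest.csv")
  writer(wm, "window_metrics.csv")
  writer(es, "epoch_summaries.csv")
  writer(ps, "participant_summaries.csv")
  st <- stage("stats", test_group_differences(
    ps,
    engine = config$engine, alpha = config$alpha,
    fdr_family = config$fdr_family, posthoc_family = config$posthoc_family,
    singular_action = config$singular_action,
    n_perm = config$n_perm, seed = config$seed
  ))
  sig <- significance_matrix(st)
  writer(st$tests, "stats_tests.csv")
  writer(st$posthoc, "stats_posthoc.csv")
  writer(sig, "significance_matrix.csv")
  if (!is.null(out)) {
    cfg <- config
    jsonlite::write_json(
      list(
        config_hash = rlang::hash(cfg),
        seed = config$seed,
        n_windows = plan$n_windows,
        n_thresholds = length(config$thresholds),
        package_version = as.character(utils::packageVersion("dynfc")),
        timestamp = format(Sys.time(), tz = "UTC")
      ),
      file.path(out, "provenance.json"),
      auto_unbox = TRUE
    )
  }
  list(
    cohort = manifest,
    window_metrics = wm,
    epoch_summaries = es,
    participant_summaries = ps,
    stats = st,
    significance = sig,
    plan = plan
  )
}
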