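#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

metric_family <- function(metric) {
  fam <- c(
    clustering = "segregation", transitivity = "segregation",
    efficiency = "integration", char_path_length = "integration",
    degree = "centrality", betweenness = "centrality",
    eccentricity = "centrality", diameter = "centrality",
    assortativity = "resilience", kcore = "resilience"
  )
  unname(fam[metric])
}

#' Diamond-grid plot of group differences
#'
#' One panel per condition x indicator (static mean vs dynamic CV); a diamond
#' marks every (network, metric) cell where the FDR-adjusted post hoc group
#' contrast is significant at one or more thresholds. Metrics are coloured by
#' family (segregation, integration, centrality, resilience).
#'
#' @param x A `"dynfc_stats"` object or the tibble from
#'   [significance_matrix()].
#' @param alpha Significance level (defaults to the object's).
#' @return A ggplot object.
#' @export
plot_significance <- function(x, alpha = NULL) {
  sig <- if (inherits(x, "dynfc_stats")) significance_matrix(x, alpha) else x
  sig <- mutate(sig,
    family = factor(
      metric_family(.data$metric),
      levels = c("segregation", "integration", "centrality", "resilience")
    ),
    metric = factor(.data$metric, levels = metric_names()),
    indicator = ifelse(.data$summary_type == "dynamic",
      "dynamic (CV)", "static (mean)"
    )
  )
  ggplot2::ggplot(sig, ggplot2::aes(x = .data$network, y = .data$metric)) +
    ggplot2::geom_point(
      data = ~ filter(.x, .data$significant),
      ggplot2::aes(colour = .data$family),
      shape = 18, size = 4
    ) +
    ggplot2::facet_grid(
      rows = ggplot2::vars(.data$indicator),
      cols = ggplot2::vars(.data$condition)
    ) +
    ggplot2::scale_y_discrete(drop = FALSE) +
    ggplot2::labs(
      x = "network", y = NULL, colour = "family",
      title = "Group differences across the threshold sweep"
    ) +
    ggplot2::theme_minimal()
}

#' @rdname plot_significance
#' @param object,... For the `autoplot()` method.
#' @method autoplot dynfc_stats
#' @export
autoplot.dynfc_stats <- function(object, ...) plot_significance(object, ...)

#' Window-to-window trajectory of a graph metric
#'
#' Plots one metric's value across sliding windows for a handful of epochs,
#' the raw material behind the static (mean) and dynamic (CV) indicators.
#'
#' @param window_metrics Long tibble from [graph_metrics()].
#' @param metric Metric to plot.
#' @param network Network to plot (default `"brain"`).
#' @param threshold Threshold to plot (default the smallest present).
#' @return A ggplot object.
#' @export
plot_metric_windows <- function(window_metrics, metric,
                                network = "brain", threshold = NULL) {
  threshold <- threshold %||% min(window_metrics$threshold)
  mt <- metric
  d <- window_metrics |>
    filter(
      .data$metric == mt, .data$network == network,
      abs(.data$threshold - !!threshold) < 1e-9
    )
  if (nrow(d) == 0) abort("No rows match the requested cell.")
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data$window, y = .data$value,
    group = interaction(.data$participant_id, .data$epoch),
    colour = .data$group
  )) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::facet_wrap(ggplot2::vars(.data$condition)) +
    ggplot2::labs(
      x = "window", y = mt,
      title = paste0(mt, " across sliding windows (", network,
        ", threshold ", threshold, ")"
      )
    ) +
    ggplot2::theme_minimal()
}
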