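#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy the group-comparison results
#'
#' @param x A `"dynfc_stats"` object from [test_group_differences()].
#' @param effects `"omnibus"` (default) returns the F-test rows; `"posthoc"`
#'   returns the per-threshold group contrasts.
#' @param ... Unused.
#' @return A tibble, one row per test.
#' @method tidy dynfc_stats
#' @export
tidy.dynfc_stats <- function(x, effects = c("omnibus", "posthoc"), ...) {
  effects <- match.arg(effects)
  if (effects == "omnibus") x$tests else x$posthoc
}

#' One-row summary of the group-comparison results
#'
#' @param x A `"dynfc_stats"` object.
#' @param ... Unused.
#' @return A one-row tibble with the engine, cell counts and the number of
#'   significant cells under the stored alpha.
#' @method glance dynfc_stats
#' @export
glance.dynfc_stats <- function(x, ...) {
  sig <- significance_matrix(x)
  tibble(
    engine = x$engine,
    n_cells = nrow(sig),
    n_significant = sum(sig$significant),
    n_skipped = nrow(x$skipped),
    alpha = x$alpha,
    fdr_family = x$fdr_family
  )
}
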