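#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up false-discovery-rate adjustment (monotone adjusted p-values), a
#' thin wrapper over [stats::p.adjust()] so the adjustment used throughout
#' the package has one documented entry point.
#'
#' @param p Numeric vector of p-values in `[0, 1]`; `NA`s are preserved.
#' @return Adjusted p-values, same length and order.
#' @examples
#' fdr_adjust(c(0.001, 0.02, 0.03, 0.5))
#' @export
fdr_adjust <- function(p) {
  if (length(p) == 0) {
    return(numeric(0))
  }
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p-values must lie in [0, 1].")
  p.adjust(p, method = "BH")
}

#' Mixed-effects ANOVA for one analysis cell
#'
#' Fits the group-comparison model for one (condition, network, metric,
#' indicator) cell: a linear mixed model with group, threshold (categorical)
#' and their interaction as fixed effects and a per-participant random
#' intercept, estimated by REML. F tests are Type III with Satterthwaite
#' denominator degrees of freedom; post hoc group contrasts are estimated
#' marginal means at each threshold (unadjusted here — the driver applies
#' FDR across the chosen family).
#'
#' A boundary ("singular") fit — the participant variance estimated at
#' zero — is expected whenever participants are exchangeable, and by default
#' is kept with a message; `singular_action = "permutation"` instead replaces
#' the group test with [permutation_group_test()].
#'
#' @param data Tibble with columns `participant_id`, `group`, `threshold`
#'   and the response.
#' @param response Name of the response column.
#' @param singular_action `"warn"` (keep the boundary fit) or
#'   `"permutation"`.
#' @param posthoc Compute the per-threshold marginal-mean contrasts (default);
#'   disable in bulk simulations that only need the omnibus tests.
#' @param n_perm,seed Used only for the permutation fallback.
#' @return List with `effects` (tibble: effect, statistic, df_num, df_den,
#'   p_value), `posthoc` (tibble: threshold, estimate, se, df, statistic,
#'   p_value), `singular`, and the `fit` object (or `NULL` after fallback).
#' @export
fit_mixed_anova <- function(data, response = "value",
                            singular_action = c("warn", "permutation"),
                            posthoc = TRUE,
                            n_perm = 999, seed = 1L) {
  singular_action <- match.arg(singular_action)
  d <- prepare_cell(data, response)
  if (sd(d$value) < 1e-12) {
    abort("Response is constant in this cell; no variance to model.")
  }
  fit <- lmerTest::lmer(
    value ~ group * threshold + (1 | participant_id),
    data = d, REML = TRUE,
    contrasts = list(group = "contr.sum", threshold = "contr.sum"),
    control = lme4::lmerControl(check.conv.singular = "ignore")
  )
  singular <- lme4::isSingular(fit)
  if (singular && singular_action == "permutation") {
    warn("Singular mixed fit; falling back to the permutation group test.")
    perm <- permutation_group_test(d,
      response = "value", n_perm = n_perm,
      seed = seed, posthoc = FALSE
    )
    return(list(
      effects = perm$effects,
      posthoc = if (posthoc) posthoc_welch(d) else NULL,
      singular = TRUE, fit = NULL
    ))
  }
  an <- anova(fit, type = 3)
  effects <- tibble(
    effect = sub("group:threshold", "group x threshold", rownames(an)),
    statistic = an[["F value"]],
    df_num = an[["NumDF"]],
    df_den = an[["DenDF"]],
    p_value = an[["Pr(>F)"]]
  )
  ph <- NULL
  if (posthoc) {
    emm <- emmeans::emmeans(fit, ~ group | threshold)
    ct <- as.data.frame(emmeans::contrast(emm, method = "pairwise", adjust = "none"))
    ph <- tibble(
      threshold = as.numeric(as.character(ct$threshold)),
      contrast = as.character(ct$contrast),
      estimate = ct$estimate,
      se = ct$SE,
      df = ct$df,
      statistic = ct$t.ratio,
      p_value = ct$p.value
    )
  }
  list(effects = effects, posthoc = ph, singular = singular, fit = fit)
}

# Common cell preparation: finite responses, factors, >= 2 participants/group.
prepare_cell <- function(data, response) {
  need <- c("participant_id", "group", "threshold", response)
  missing <- setdiff(need, names(data))
  if (length(missing) > 0) {
    abort(paste0("Missing columns: ", paste(missing, collapse = ", ")))
  }
  d <- data[, need]
  names(d)[names(d) == response] <- "value"
  n_drop <- sum(!is.finite(d$value))
  if (n_drop > 0) {
    inform(paste0("Dropping ", n_drop, " non-finite response value(s)."))
    d <- d[is.finite(d$value), ]
  }
  if (nrow(d) == 0) abort("No finite responses in this cell.")
  d$group <- factor(d$group)
  d$threshold <- factor(d$threshold)
  d$participant_id <- factor(d$participant_id)
  counts <- table(unique(d[, c("participant_id", "group")])$group)
  if (length(counts) < 2 || any(counts < 2)) {
    abort("Need >= 2 participants in each of >= 2 groups.")
  }
  d
}

# Per-threshold Welch two-sample contrasts (post hoc surrogate when no mixed
# fit is available).
posthoc_welch <- function(d) {
  gl <- levels(d$group)
  purrr::map_dfr(levels(d$threshold), function(th) {
    dt <- d[d$threshold == th, ]
    tt <- stats::t.test(value ~ group, data = dt)
    tibble(
      threshold = as.numeric(th),
      contrast = paste(gl, collapse = " - "),
      estimate = unname(diff(rev(tt$estimate))),
      se = tt$stderr,
      df = unname(tt$parameter),
      statistic = unname(tt$statistic),
      p_value = tt$p.value
    )
  })
}

#' Participant-level permutation test of the group effect
#'
#' A distribution-free companion to the mixed model: the test statistic is
#' the group F from an ordinary two-way (group x threshold) least-squares
#' fit, and the null distribution is built by permuting group labels across
#' participants — each participant's thresholds travel together, respecting
#' exchangeability at the participant level. When the number of distinct
#' balanced assignments is at most `n_perm`, the test enumerates them all
#' (exact); otherwise it samples `n_perm` permutations and reports
#' `p = (1 + #(F_perm >= F_obs)) / (1 + n_perm)`.
#'
#' @inheritParams fit_mixed_anova
#' @param n_perm Number of sampled permutations (>= 99).
#' @param seed RNG seed for the sampled-permutation branch.
#' @param posthoc Compute per-threshold Welch contrasts (default).
#' @return List with `effects` (one-row tibble for the group effect:
#'   statistic, p_value, n_perm, exact) and `posthoc` (per-threshold Welch
#'   contrasts).
#' @export
permutation_group_test <- function(data, response = "value",
                                   n_perm = 999, seed = 1L, posthoc = TRUE) {
  if (n_perm < 99) abort("`n_perm` must be >= 99.")
  d <- prepare_cell(data, response)
  pt <- unique(d[, c("participant_id", "group")])
  ids <- as.character(pt$participant_id)
  gl <- levels(d$group)
  n1 <- sum(pt$group == gl[1])
  row_id <- match(as.character(d$participant_id), ids)
  value <- d$value
  n <- length(value)
  # Cell-means RSS of the full group x threshold fit is permutation-invariant
  # only in its threshold part; recompute the group and cell terms per
  # permutation from grouped sums (algebraically identical to the sequential
  # F of `group` in anova(lm(value ~ group * threshold))).
  th_int <- as.integer(d$threshold)
  n_th <- nlevels(d$threshold)
  rss_null <- sum((value - mean(value))^2)
  group_f <- function(assign_g1) {
    g1 <- row_id %in% match(assign_g1, ids)
    cell <- th_int + n_th * g1 # 1..2*n_th cell codes
    gm <- c(mean(value[g1]), mean(value[!g1]))
    rss_group <- sum((value[g1] - gm[1])^2) + sum((value[!g1] - gm[2])^2)
    cm <- tapply(value, cell, mean)
    fitted_cell <- cm[as.character(cell)]
    rss_full <- sum((value - fitted_cell)^2)
    df_res <- n - length(cm)
    ((rss_null - rss_group) / 1) / (rss_full / df_res)
  }
  f_obs <- group_f(ids[pt$group == gl[1]])
  n_total <- choose(length(ids), n1)
  if (n_total <= n_perm) {
    assigns <- utils::combn(ids, n1, simplify = FALSE)
    f_all <- vapply(assigns, group_f, numeric(1))
    p <- mean(f_all >= f_obs - 1e-12)
    exact <- TRUE
    n_used <- n_total
  } else {
    f_perm <- withr::with_seed(seed, vapply(seq_len(n_perm), function(i) {
      group_f(sample(ids, n1))
    }, numeric(1)))
    p <- (1 + sum(f_perm >= f_obs - 1e-12)) / (1 + n_perm)
    exact <- FALSE
    n_used <- n_perm
  }
  effects <- tibble(
    effect = "group",
    statistic = f_obs,
    df_num = NA_real_,
    df_den = NA_real_,
    p_value = p,
    n_perm = n_used,
    exact = exact
  )
  list(effects = effects, posthoc = if (posthoc) posthoc_welch(d) else NULL)
}

#' Group-level inference across all analysis cells
#'
#' Runs the group comparison over every (condition, network, metric) cell for
#' the static (`static_mean`) and dynamic (`dynamic_cv`) indicators,
#' modelling each condition and indicator separately, then applies
#' Benjamini-Hochberg FDR. The omnibus family is, by default, all
#' (network, metric, effect) rows within one (condition, indicator) stratum;
#' post hoc group contrasts are adjusted across thresholds within each
#' (network, metric) cell (`posthoc_family = "within_metric"`) or across the
#' whole stratum (`"stratum"`).
#'
#' @param participant_summaries Tibble from [aggregate_participants()] (or
#'   [summarize_windows()] with `pool_epochs = TRUE`).
#' @param responses Which indicators to analyse.
#' @param engine `"mixed"` ([fit_mixed_anova()]) or `"permutation"`
#'   ([permutation_group_test()]).
#' @param alpha Significance level used by [significance_matrix()].
#' @param fdr_family `"stratum"` (default) or `"global"` family for the
#'   omnibus F tests.
#' @param posthoc_family `"within_metric"` (default) or `"stratum"`.
#' @param singular_action,n_perm,seed Passed to the engines; per-cell seeds
#'   are derived from `seed` so results are reproducible.
#' @return Object of class `"dynfc_stats"`: list with `tests` (one row per
#'   cell x effect, with `p_adjusted`), `posthoc` (per-threshold contrasts
#'   with `p_adjusted`), `skipped` (cells that could not be modelled), plus
#'   the settings. Supports [generics::tidy()], [generics::glance()],
#'   [significance_matrix()] and [ggplot2::autoplot()].
#' @export
test_group_differences <- function(participant_summaries,
                                   responses = c("static_mean", "dynamic_cv"),
                                   engine = c("mixed", "permutation"),
                                   alpha = 0.05,
                                   fdr_family = c("stratum", "global"),
                                   posthoc_family = c("within_metric", "stratum"),
                                   singular_action = c("warn", "permutation"),
                                   n_perm = 999, seed = 1L) {
  engine <- match.arg(engine)
  fdr_family <- match.arg(fdr_family)
  posthoc_family <- match.arg(posthoc_family)
  singular_action <- match.arg(singular_action)
  responses <- match.arg(responses, c("static_mean", "dynamic_cv"),
    several.ok = TRUE
  )
  label <- c(static_mean = "static", dynamic_cv = "dynamic")
  cells <- distinct(
    participant_summaries,
    .data$condition, .data$network, .data$metric
  )
  tests <- list()
  posthoc <- list()
  skipped <- list()
  cell_i <- 0L
  for (resp in responses) {
    for (r in seq_len(nrow(cells))) {
      cell_i <- cell_i + 1L
      cd <- cells$condition[r]
      nw <- cells$network[r]
      mt <- cells$metric[r]
      d <- participant_summaries |>
        filter(
          .data$condition == cd, .data$network == nw, .data$metric == mt
        )
      cell_seed <- derive_seed(seed, cell_i, 1L, 1L)
      res <- tryCatch(
        {
          if (engine == "mixed") {
            suppressMessages(fit_mixed_anova(d,
              response = resp,
              singular_action = singular_action,
              n_perm = n_perm, seed = cell_seed
            ))
          } else {
            suppressMessages(permutation_group_test(d,
              response = resp,
              n_perm = n_perm, seed = cell_seed
            ))
          }
        },
        error = function(e) e
      )
      key <- tibble(
        condition = cd, network = nw, metric = mt,
        summary_type = unname(label[resp])
      )
      if (inherits(res, "error")) {
        skipped[[length(skipped) + 1L]] <-
          mutate(key, reason = conditionMessage(res))
        next
      }
      tests[[length(tests) + 1L]] <- dplyr::bind_cols(
        key[rep(1, nrow(res$effects)), ], res$effects
      )
      posthoc[[length(posthoc) + 1L]] <- dplyr::bind_cols(
        key[rep(1, nrow(res$posthoc)), ], res$posthoc
      )
    }
  }
  tests <- dplyr::bind_rows(tests)
  posthoc <- dplyr::bind_rows(posthoc)
  if (nrow(tests) > 0) {
    grp <- if (fdr_family == "stratum") c("condition", "summary_type") else character(0)
    tests <- tests |>
      group_by(across(dplyr::all_of(grp))) |>
      mutate(p_adjusted = fdr_adjust(.data$p_value)) |>
      ungroup()
  }
  if (nrow(posthoc) > 0) {
    grp <- if (posthoc_family == "within_metric") {
      c("condition", "summary_type", "network", "metric")
    } else {
      c("condition", "summary_type")
    }
    posthoc <- posthoc |>
      group_by(across(dplyr::all_of(grp))) |>
      mutate(p_adjusted = fdr_adjust(.data$p_value)) |>
      ungroup()
  }
  structure(
    list(
      tests = tests, posthoc = posthoc,
      skipped = dplyr::bind_rows(skipped),
      alpha = alpha, engine = engine,
      fdr_family = fdr_family, posthoc_family = posthoc_family
    ),
    class = "dynfc_stats"
  )
}

#' Significance matrix (the "diamond" summary)
#'
#' Marks a (condition, network, metric, indicator) cell significant iff at
#' least one threshold's FDR-adjusted post hoc group contrast falls below
#' `alpha` — i.e. a group difference appears at one or more thresholds.
#'
#' @param x A `"dynfc_stats"` object.
#' @param alpha Significance level (defaults to the level stored in `x`).
#' @return Tibble with columns `condition`, `network`, `metric`,
#'   `summary_type`, `n_sig_thresholds`, `significant`.
#' @export
significance_matrix <- function(x, alpha = NULL) {
  stopifnot(inherits(x, "dynfc_stats"))
  alpha <- alpha %||% x$alpha
  x$posthoc |>
    group_by(
      .data$condition, .data$network, .data$metric, .data$summary_type
    ) |>
    summarise(
      n_sig_thresholds = sum(.data$p_adjusted < alpha, na.rm = TRUE),
      significant = .data$n_sig_thresholds > 0,
      .groups = "drop"
    )
}

#' @export
print.dynfc_stats <- function(x, ...) {
  cat("<dynfc_stats> engine: ", x$engine, ", ", nrow(x$tests),
    " effect rows, ", nrow(x$posthoc), " post hoc contrasts",
    if (nrow(x$skipped) > 0) paste0(", ", nrow(x$skipped), " cells skipped"),
    "\n",
    sep = ""
  )
  sig <- significance_matrix(x)
  cat(
    sum(sig$significant), " of ", nrow(sig),
    " cells significant at alpha = ", x$alpha, "\n",
    sep = ""
  )
  invisible(x)
}
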