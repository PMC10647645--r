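# Participant-level summary tables built directly, so the inference layer is
# tested on data with known structure, independent of the simulation stack.
make_summary_table <- function(n_per_group = 8, group_shift = 0,
                               participant_sd = 1, resid_sd = 1, seed = 1,
                               thresholds = default_thresholds()) {
  withr::with_seed(seed, {
    ids <- sprintf("P%02d", seq_len(2 * n_per_group))
    groups <- rep(c("SZ", "HC"), each = n_per_group)
    intercepts <- rnorm(length(ids), sd = participant_sd)
    d <- tidyr::expand_grid(i = seq_along(ids), threshold = thresholds)
    tibble::tibble(
      participant_id = ids[d$i],
      group = groups[d$i],
      condition = "OT",
      network = "brain",
      metric = "efficiency",
      threshold = d$threshold,
      static_mean = 10 + intercepts[d$i] + rnorm(nrow(d), sd = resid_sd) +
        ifelse(groups[d$i] == "SZ", group_shift, 0),
      dynamic_cv = 30 + rnorm(nrow(d), sd = resid_sd)
    )
  })
}

test_that("BH adjustment matches the hand-applied step-up rule", {
  expect_equal(
    fdr_adjust(c(0.001, 0.02, 0.03, 0.5)),
    c(0.004, 0.04, 0.04, 0.5)
  )
  expect_equal(fdr_adjust(0.2), 0.2)
  expect_equal(fdr_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(fdr_adjust(numeric(0)), numeric(0))
  expect_error(fdr_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("BH adjustment never lowers a p-value and preserves ranking", {
  withr::with_seed(6, {
    for (i in 1:20) {
      p <- runif(sample(2:30, 1))
      q <- fdr_adjust(p)
      expect_true(all(q >= p))
      expect_true(all(q <= 1))
      # ranking preserved: sorted p implies sorted q
      expect_true(all(diff(q[order(p)]) >= -1e-15))
    }
  })
})

test_that("mixed ANOVA recovers an injected group shift", {
  tbl <- make_summary_table(n_per_group = 10, group_shift = 1.5, seed = 42)
  fit <- suppressMessages(fit_mixed_anova(tbl, response = "static_mean"))
  expect_setequal(
    fit$effects$effect,
    c("group", "threshold", "group x threshold")
  )
  p_group <- fit$effects$p_value[fit$effects$effect == "group"]
  expect_lt(p_group, 0.05)
  # post hoc contrasts: one per threshold; the HC - SZ estimate should sit
  # near -1.5 (the shift was added to SZ), within sampling error of the
  # participant intercepts
  expect_equal(nrow(fit$posthoc), 6)
  expect_equal(sort(fit$posthoc$threshold), default_thresholds())
  expect_match(fit$posthoc$contrast[1], "HC - SZ")
  expect_lt(abs(mean(fit$posthoc$estimate) - (-1.5)), 1.2)
  # null response in the same table stays quiet
  fit0 <- suppressMessages(fit_mixed_anova(tbl, response = "dynamic_cv"))
  expect_gt(fit0$effects$p_value[fit0$effects$effect == "group"], 0.05)
})

test_that("constant responses are rejected as unmodelable", {
  tbl <- make_summary_table(n_per_group = 3)
  tbl$static_mean <- 5
  expect_error(
    suppressMessages(fit_mixed_anova(tbl, response = "static_mean")),
    "constant"
  )
})

test_that("the singular-fit permutation fallback engages on request", {
  # no participant variance at all: the REML fit sits on the boundary
  tbl <- make_summary_table(n_per_group = 5, participant_sd = 0, seed = 11)
  expect_warning(
    fit <- suppressMessages(fit_mixed_anova(tbl,
      response = "static_mean",
      singular_action = "permutation", n_perm = 199, seed = 3
    )),
    "permutation"
  )
  expect_true(fit$singular)
  expect_null(fit$fit)
  expect_true("n_perm" %in% names(fit$effects))
})

test_that("permutation F equals the ordinary two-way ANOVA F", {
  tbl <- make_summary_table(n_per_group = 6, group_shift = 1, seed = 7)
  d <- tbl
  d$group <- factor(d$group)
  d$threshold <- factor(d$threshold)
  f_ref <- anova(
    lm(static_mean ~ group * threshold, data = d)
  )["group", "F value"]
  res <- suppressMessages(
    permutation_group_test(tbl, response = "static_mean", n_perm = 99)
  )
  expect_equal(res$effects$statistic, f_ref, tolerance = 1e-10)
})

test_that("small cohorts are tested by exact enumeration", {
  tbl <- make_summary_table(n_per_group = 3, group_shift = 3, seed = 2)
  res <- suppressMessages(
    permutation_group_test(tbl, response = "static_mean", n_perm = 999)
  )
  expect_true(res$effects$exact)
  expect_equal(res$effects$n_perm, choose(6, 3)) # 20 balanced assignments
  # the smallest attainable exact p is 2/20 (observed split and its mirror)
  expect_gte(res$effects$p_value, 2 / 20 - 1e-12)
  res2 <- suppressMessages(
    permutation_group_test(tbl, response = "static_mean", n_perm = 999)
  )
  expect_identical(res$effects$p_value, res2$effects$p_value)
})

test_that("sampled permutation p-values are deterministic in the seed", {
  tbl <- make_summary_table(n_per_group = 8, group_shift = 0.5, seed = 9)
  r1 <- suppressMessages(
    permutation_group_test(tbl, response = "static_mean", n_perm = 199, seed = 5)
  )
  r2 <- suppressMessages(
    permutation_group_test(tbl, response = "static_mean", n_perm = 199, seed = 5)
  )
  r3 <- suppressMessages(
    permutation_group_test(tbl, response = "static_mean", n_perm = 199, seed = 6)
  )
  expect_identical(r1$effects$p_value, r2$effects$p_value)
  expect_false(r1$effects$exact)
  expect_gte(r3$effects$p_value, 1 / 200)
})

test_that("the driver adjusts within strata and builds the diamond matrix", {
  tbl <- dplyr::bind_rows(
    make_summary_table(n_per_group = 8, group_shift = 2, seed = 21),
    make_summary_table(n_per_group = 8, group_shift = 0, seed = 22) |>
      mutate(metric = "clustering")
  )
  res <- suppressWarnings(suppressMessages(test_group_differences(tbl)))
  expect_s3_class(res, "dynfc_stats")
  expect_equal(nrow(res$tests), 2 * 2 * 3) # 2 metrics x 2 indicators x 3 effects
  expect_true(all(res$tests$p_adjusted >= res$tests$p_value))
  expect_true(all(res$tests$p_adjusted <= 1))
  sig <- significance_matrix(res)
  expect_equal(nrow(sig), 4)
  # the shifted static efficiency cell is flagged, its null partner is not
  expect_true(
    sig$significant[sig$metric == "efficiency" & sig$summary_type == "static"]
  )
  expect_false(
    sig$significant[sig$metric == "clustering" & sig$summary_type == "static"]
  )
  # diamond rule: significant iff any threshold contrast survives FDR
  flagged <- res$posthoc |>
    dplyr::group_by(condition, network, metric, summary_type) |>
    dplyr::summarise(any_sig = any(p_adjusted < 0.05), .groups = "drop")
  expect_equal(sig$significant, flagged$any_sig)
  # tidy/glance accessors
  expect_equal(nrow(tidy(res)), nrow(res$tests))
  expect_equal(glance(res)$n_cells, 4)
  expect_s3_class(plot_significance(res), "ggplot")
  expect_s3_class(ggplot2::autoplot(res), "ggplot")
})

test_that("cells that cannot be modelled are reported as skipped", {
  tbl <- make_summary_table(n_per_group = 4, seed = 30)
  tbl$dynamic_cv <- 7 # constant: unmodelable
  res <- suppressMessages(test_group_differences(tbl))
  expect_equal(nrow(res$skipped), 1)
  expect_match(res$skipped$reason, "constant")
  expect_equal(nrow(res$tests), 3) # static cell still analysed
})
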