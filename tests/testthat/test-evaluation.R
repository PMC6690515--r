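test_that("proportion_below uses strict inequality and validates input", {
  expect_equal(proportion_below(c(0.01, 0.04, 0.2, 0.9), 0.05), 0.5)
  expect_equal(proportion_below(rep(1, 10), 0.05), 0)
  expect_equal(proportion_below(c(0.05, 0.06), 0.05), 0) # strict
  expect_error(proportion_below(numeric(0)), "empty")
  expect_error(proportion_below(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(1)
  expect_lt(abs(proportion_below(stats::runif(1e5), 0.05) - 0.05), 0.002)
})

test_that("uniformity check separates calibrated from broken null p-values", {
  set.seed(2)
  u <- stats::runif(1000)
  expect_gt(uniformity_check(u)$p_value, 0.01)
  expect_lt(uniformity_check(stats::runif(1000, 0, 0.05))$p_value, 1e-10)
  expect_error(uniformity_check(stats::runif(50)), "at least 100")
  expect_error(uniformity_check(c(rep(0.5, 100), 1.5)), "\\[0, 1\\]")
})

test_that("p-value histogram uses 20 right-open 0.05 bins with proportions", {
  p <- c(0, 0.049, 0.05, 0.51, 0.999, 1)
  h <- pvalue_histogram(p)
  expect_equal(nrow(h), 20)
  expect_equal(sum(h$proportion), 1)
  expect_equal(h$proportion[1], 2 / 6)   # 0 and 0.049; 0.05 falls in bin 2
  expect_equal(h$proportion[2], 1 / 6)
  expect_equal(h$proportion[20], 2 / 6)  # 0.999 and the closed right edge 1
  # first-bin proportion is the rejection rate at alpha = 0.05
  set.seed(3)
  u <- stats::runif(500)
  expect_equal(pvalue_histogram(u)$proportion[1], proportion_below(u, 0.05))
})

test_that("SEM summaries expose the constant-vs-increasing structure", {
  sm <- run_scenario(fixture_params, fixture_scenario("null", n_reps = 25))
  wk <- function(m, t) sm$sem_draws[[which(sm$method == m & sm$test_id == t)]]
  # homogeneous fit: identical SEM at every week within each replicate
  expect_equal(wk("rma_homogeneous", "week1"), wk("rma_homogeneous", "week28"),
               tolerance = 1e-10)
  # heterogeneous fit and separate ANOVA both track the rising variance
  expect_gt(mean(wk("rma_correct", "week28")), mean(wk("rma_correct", "week1")))
  expect_gt(mean(wk("separate_anova", "week28")),
            mean(wk("separate_anova", "week1")))
  s <- summarize_sems(wk("rma_correct", "week1"))
  expect_equal(nrow(s$histogram), 20)
  expect_equal(sum(s$histogram$proportion), 1)
  expect_error(summarize_sems(numeric(0)), "empty")
  expect_error(summarize_sems(c(1, -1)), "positive")
})

test_that("run_scenario summarises all three methods over common replicates", {
  sc <- fixture_scenario("null", n_per_group = 6, n_reps = 8)
  sm <- run_scenario(fixture_params, sc)
  expect_s3_class(sm, "rma_summary")
  expect_setequal(unique(sm$method),
                  c("rma_correct", "rma_homogeneous", "separate_anova"))
  # RMA methods carry 8 tests, separate ANOVA only the 5 per-week ones
  expect_equal(sum(sm$method == "rma_correct"), 8)
  expect_equal(sum(sm$method == "separate_anova"), 5)
  expect_true(all(purrr::map_int(sm$p_values, length) == sm$n_converged))
  expect_true(all(sm$rejection_rate >= 0 & sm$rejection_rate <= 1))
  expect_equal(sm$rejection_rate,
               purrr::map_dbl(sm$p_values, proportion_below, alpha = 0.05))

  # single replicate: rate is 0 or 1
  sm1 <- run_scenario(fixture_params, fixture_scenario("null", n_reps = 1))
  expect_true(all(sm1$rejection_rate %in% c(0, 1)))

  # rerun reproduces identical summaries (common random numbers)
  sm2 <- run_scenario(fixture_params, sc)
  expect_equal(sm$rejection_rate, sm2$rejection_rate)
  expect_equal(sm$p_values, sm2$p_values)
})

test_that("summary_table flattens a scenario run for export", {
  sc <- fixture_scenario("alternative", n_per_group = 3, n_reps = 4)
  st <- summary_table(run_scenario(fixture_params, sc))
  expect_false(any(c("p_values", "sem_draws") %in% names(st)))
  expect_equal(unique(st$hypothesis), "alternative")
  expect_equal(unique(st$n_per_group), 3L)
})

test_that("plot builders return ggplot objects", {
  sm <- run_scenario(fixture_params, fixture_scenario("null", n_reps = 6))
  expect_s3_class(plot_pvalue_grid(sm), "ggplot")
  expect_s3_class(plot_sem_grid(sm), "ggplot")
  expect_s3_class(ggplot2::autoplot(sm, "sems"), "ggplot")
})
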