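# Monte-Carlo loop: simulate a scenario, analyze each replicate three ways,
# summarize p-value and SEM behaviour.

hom_counterpart <- function(truth) {
  switch(truth, het_cs = "hom_cs", het_ar1 = "hom_ar1",
         stop("no homogeneous counterpart for ", truth))
}

# lean per-fit test battery for the simulation loop: overall effects plus the
# joint per-week treatment contrast and the pairwise SEM at every week
fit_test_battery <- function(fit, ddf) {
  overall <- test_fixed_effects(fit, ddf = ddf)
  weeks <- purrr::map(seq_len(fit$n_time), function(t) {
    L <- time_contrast_matrix(t, fit$n_groups, fit$n_time)
    w <- wald_test(fit, L, ddf, within = FALSE)
    w$test_id <- paste0("week", fit$weeks[t])
    # pairwise SEM: equal across pairs under a pooled structure with equal n
    w$sem <- sqrt(2 * fit$sigma[t, t] / fit$n_per_group[1])
    w
  })
  tibble::tibble(
    test_id = c(overall$effect, paste0("week", fit$weeks)),
    p_value = c(overall$p_value, vapply(weeks, `[[`, numeric(1), "p_value")),
    sem = c(rep(NA_real_, 3), vapply(weeks, `[[`, numeric(1), "sem"))
  )
}

#' Run the full simulation-analysis loop for one scenario
#'
#' For each replicate: simulate one balanced dataset, then analyze it three
#' ways on the identical data (common random numbers): (i) REML with the
#' correctly specified heterogeneous structure, (ii) REML with its homogeneous
#' (constant-variance) counterpart, (iii) separate one-way ANOVA at each time
#' point. Collects p-values for the overall treatment, time and interaction
#' tests and the per-week joint treatment contrasts, plus the per-week
#' pairwise SEM draws.
#'
#' Replicates whose REML fit fails to converge are dropped from that method's
#' rejection-rate denominator; a warning is raised if more than 1% of
#' replicates are excluded for any method.
#'
#' @param params Parameter table, as from [param_table()].
#' @param sc A [scenario()].
#' @param ddf Denominator df method for the REML-based tests.
#' @param progress Print a dot every 100 replicates.
#' @return A tibble with one row per method x test: `method` (`rma_correct`,
#'   `rma_homogeneous`, `separate_anova`), `test_id` (`treatment`, `time`,
#'   `interaction`, `week1` ... `week28`), `n_reps`, `n_converged`,
#'   `rejection_rate` (share of p-values strictly below `sc$alpha`),
#'   `mean_sem`, and list-columns `p_values`, `sem_draws`.
#' @examples
#' sc <- scenario("het_cs", 12, 0.3, "null", n_reps = 5)
#' run_scenario(param_table(), sc)
#' @export
run_scenario <- function(params, sc, ddf = "satterthwaite", progress = FALSE) {
  stopifnot(inherits(sc, "rma_scenario"))
  hom_kind <- hom_counterpart(sc$truth)
  reps <- purrr::map(seq_len(sc$n_reps), function(r) {
    if (progress && r %% 100 == 0) cat(".")
    data <- simulate_dataset(params, sc, r)
    out <- list()
    for (m in c("rma_correct", "rma_homogeneous")) {
      kind <- if (m == "rma_correct") sc$truth else hom_kind
      fit <- fit_gls_reml(data, kind, ddf = ddf)
      if (fit$converged) {
        b <- suppressWarnings(fit_test_battery(fit, ddf))
        b$method <- m
        out[[m]] <- b
      }
    }
    a <- anova_all_times(data)
    out$separate_anova <- tibble::tibble(
      test_id = paste0("week", a$week), p_value = a$p_value, sem = a$sem,
      method = "separate_anova")
    dplyr::bind_rows(out)
  })
  if (progress) cat("\n")
  all <- dplyr::bind_rows(reps)
  out <- all |>
    dplyr::group_by(.data$method, .data$test_id) |>
    dplyr::summarise(
      n_reps = sc$n_reps,
      n_converged = dplyr::n(),
      rejection_rate = proportion_below(.data$p_value, sc$alpha),
      mean_sem = mean(.data$sem),
      p_values = list(.data$p_value),
      sem_draws = list(.data$sem),
      .groups = "drop"
    )
  bad <- out$n_converged < 0.99 * sc$n_reps
  if (any(bad)) {
    warning(sprintf(
      "more than 1%% of replicates excluded for non-convergence (%s)",
      paste(unique(out$method[bad]), collapse = ", ")))
  }
  test_order <- c("treatment", "time", "interaction",
                  paste0("week", week_labels()))
  out$test_id <- factor(out$test_id, levels = test_order)
  out <- dplyr::arrange(out, .data$method, .data$test_id)
  out$test_id <- as.character(out$test_id)
  tibble::new_tibble(out, scenario = sc, class = "rma_summary")
}

#' Proportion of p-values below a threshold
#'
#' Strict inequality, matching rejection at level `alpha`.
#'
#' @param p_values Vector of p-values in `[0, 1]`.
#' @param alpha Threshold (default 0.05).
#' @return A proportion.
#' @examples
#' proportion_below(c(0.01, 0.04, 0.2, 0.9)) # 0.5
#' @export
proportion_below <- function(p_values, alpha = 0.05) {
  if (length(p_values) == 0) stop("empty p-value vector")
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  mean(p_values < alpha, na.rm = TRUE)
}

#' Kolmogorov-Smirnov uniformity check for null p-values
#'
#' A correctly calibrated test produces p-values uniform on (0, 1) under the
#' null; this runs a one-sample KS test against that reference.
#'
#' @param p_values Vector of at least 100 p-values in `[0, 1]`.
#' @return A one-row tibble: `statistic` (KS D), `p_value`.
#' @export
uniformity_check <- function(p_values) {
  if (length(p_values) < 100) stop("need at least 100 p-values")
  if (any(p_values < 0 | p_values > 1)) stop("p-values must lie in [0, 1]")
  ks <- suppressWarnings(stats::ks.test(p_values, "punif"))
  tibble::tibble(statistic = unname(ks$statistic), p_value = ks$p.value)
}

#' Histogram of p-values in 0.05-wide bins
#'
#' Twenty bins of width 0.05 on `[0, 1]`, right-open except the last, with
#' counts normalized by the number of (converged) replicates, so the first
#' bin's proportion is the rejection rate at alpha = 0.05.
#'
#' @param p_values Vector of p-values in `[0, 1]`.
#' @return A tibble: `bin_lower`, `bin_upper`, `proportion`.
#' @export
pvalue_histogram <- function(p_values) {
  if (length(p_values) == 0) stop("empty p-value vector")
  if (any(p_values < 0 | p_values > 1)) stop("p-values must lie in [0, 1]")
  bin <- pmin(floor(p_values / 0.05) + 1, 20)
  counts <- tabulate(bin, nbins = 20)
  tibble::tibble(
    bin_lower = seq(0, 0.95, by = 0.05),
    bin_upper = seq(0.05, 1, by = 0.05),
    proportion = counts / length(p_values)
  )
}

#' Summarise pairwise-SEM draws
#'
#' @param sem_draws Vector of positive SEM draws (grams).
#' @param n_bins Number of histogram bins on the data range (default 20).
#' @return A list with `mean`, `sd` and a `histogram` tibble
#'   (`bin_lower`, `bin_upper`, `proportion`).
#' @export
summarize_sems <- function(sem_draws, n_bins = 20) {
  if (length(sem_draws) == 0) stop("empty SEM vector")
  if (any(sem_draws <= 0)) stop("SEMs must be positive")
  edges <- seq(min(sem_draws), max(sem_draws), length.out = n_bins + 1)
  if (edges[1] == edges[n_bins + 1]) edges <- edges[1] + c(-0.5, 0.5) * 1e-8
  bin <- pmin(findInterval(sem_draws, edges), length(edges) - 1)
  counts <- tabulate(bin, nbins = length(edges) - 1)
  list(
    mean = mean(sem_draws), sd = stats::sd(sem_draws),
    histogram = tibble::tibble(
      bin_lower = edges[-length(edges)], bin_upper = edges[-1],
      proportion = counts / length(sem_draws))
  )
}

#' Flatten a scenario summary for export
#'
#' Drops the per-replicate list-columns, yielding the tidy per-test CSV rows.
#'
#' @param summary An [run_scenario()] result.
#' @return A plain tibble with the scenario descriptors and per-test rates.
#' @export
summary_table <- function(summary) {
  sc <- attr(summary, "scenario")
  dplyr::bind_cols(
    tibble::tibble(truth = sc$truth, hypothesis = sc$hypothesis,
                   n_per_group = sc$n_per_group, rho = sc$rho,
                   alpha = sc$alpha),
    dplyr::select(tibble::as_tibble(summary), -"p_values", -"sem_draws")
  )
}
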