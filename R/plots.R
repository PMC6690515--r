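#' Plot p-value distributions for a scenario summary
#'
#' Recreates the diagnostic grid of p-value histograms: one panel per test,
#' one row per analysis method, bins of width 0.05 with proportions on the
#' y axis. Under a calibrated null every panel should look flat at 0.05.
#'
#' @param summary An [run_scenario()] result.
#' @param tests Which tests to show (default: the five per-week contrasts).
#' @return A ggplot object.
#' @export
plot_pvalue_grid <- function(summary, tests = paste0("week", week_labels())) {
  df <- summary |>
    dplyr::filter(.data$test_id %in% tests) |>
    dplyr::mutate(hist = purrr::map(.data$p_values, pvalue_histogram)) |>
    dplyr::select("method", "test_id", "hist") |>
    tidyr::unnest("hist")
  df$test_id <- factor(df$test_id, levels = tests)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin_lower + 0.025,
                                   y = .data$proportion)) +
    ggplot2::geom_col(width = 0.05, fill = "grey35") +
    ggplot2::geom_hline(yintercept = 0.05, linetype = "dashed",
                        colour = "red3") +
    ggplot2::facet_grid(method ~ test_id) +
    ggplot2::labs(x = "p-value", y = "proportion of replicates") +
    ggplot2::theme_bw()
}

#' Plot SEM distributions for a scenario summary
#'
#' Distributions of the per-replicate pairwise SEM at each week, by analysis
#' method. Homogeneous-structure fits show one common distribution across
#' weeks; heterogeneous fits and separate ANOVAs track the increasing
#' variance over time.
#'
#' @param summary An [run_scenario()] result.
#' @return A ggplot object.
#' @export
plot_sem_grid <- function(summary) {
  df <- summary |>
    dplyr::filter(grepl("^week", .data$test_id)) |>
    dplyr::select("method", "test_id", "sem_draws") |>
    tidyr::unnest("sem_draws")
  df$test_id <- factor(df$test_id, levels = paste0("week", week_labels()))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sem_draws)) +
    ggplot2::geom_histogram(bins = 20, fill = "grey35") +
    ggplot2::facet_grid(method ~ test_id, scales = "free_x") +
    ggplot2::labs(x = "SEM for pairwise treatment comparison (g)",
                  y = "replicates") +
    ggplot2::theme_bw()
}

#' Autoplot a scenario summary
#'
#' @param object An [run_scenario()] result.
#' @param type `"pvalues"` for the p-value histogram grid, `"sems"` for the
#'   SEM distribution grid.
#' @param ... Unused.
#' @return A ggplot object.
#' @importFrom ggplot2 autoplot
#' @method autoplot rma_summary
#' @export
autoplot.rma_summary <- function(object, type = c("pvalues", "sems"), ...) {
  type <- match.arg(type)
  if (type == "pvalues") plot_pvalue_grid(object) else plot_sem_grid(object)
}
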