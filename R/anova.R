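#' Separate one-way ANOVA at a single time point
#'
#' The third analysis approach: ignore the repeated-measures structure and
#' test the treatment effect at one time point with a classical one-way ANOVA
#' using only that time point's observations. F = MSB/MSE on
#' (G - 1, G(n - 1)) df via [stats::lm()]/[stats::anova()]; the SEM for
#' comparing two treatment means is `sqrt(2 * MSE / n)`.
#'
#' @param data Long-format balanced dataset.
#' @param time_index Time-point position, 1-based.
#' @return A one-row tibble: `time_index`, `week`, `statistic`, `df_num`,
#'   `df_den`, `p_value`, `mse` (grams^2), `sem` (grams).
#' @examples
#' d <- simulate_dataset(param_table(), scenario("het_cs", 6, 0.3, "null"), 1)
#' anova_at_time(d, 5)
#' @export
anova_at_time <- function(data, time_index) {
  d <- data[data$time_index == time_index, , drop = FALSE]
  if (nrow(d) == 0) stop("`time_index` out of range")
  d$treatment <- droplevels(factor(d$treatment))
  if (nlevels(d$treatment) < 2) stop("need at least two treatment arms")
  n_per <- table(d$treatment)
  if (any(n_per < 2)) stop("need at least two subjects per arm")
  # perfect-fit warnings surface as the degenerate-MSE error below
  tab <- suppressWarnings(stats::anova(stats::lm(response ~ treatment,
                                                 data = d)))
  mse <- tab["Residuals", "Mean Sq"]
  if (mse <= 0) stop("degenerate data: zero residual variance at this time point")
  tibble::tibble(
    time_index = as.integer(time_index),
    week = if ("week" %in% names(d)) d$week[1] else NA_integer_,
    statistic = tab["treatment", "F value"],
    df_num = tab["treatment", "Df"],
    df_den = tab["Residuals", "Df"],
    p_value = tab["treatment", "Pr(>F)"],
    mse = mse,
    sem = sqrt(2 * mse / min(n_per))
  )
}

#' Separate ANOVAs at every time point
#'
#' @param data Long-format balanced dataset.
#' @return A tibble with one [anova_at_time()] row per time point.
#' @export
anova_all_times <- function(data) {
  dplyr::bind_rows(lapply(sort(unique(data$time_index)), anova_at_time,
                          data = data))
}
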