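#' Treatment arm labels
#'
#' The three dietary treatment arms of the mouse body-weight experiment the
#' simulations emulate: 10-fold folate diet for mother and pup (HFol-HFol),
#' 10-fold folate for mother with recommended vitamins for the pup (HFol-RV),
#' and recommended vitamins for both (RV-RV).
#'
#' @return Character vector of the three arm labels, in fixed order.
#' @export
arm_labels <- function() c("HFol-HFol", "HFol-RV", "RV-RV")

#' Measurement weeks
#'
#' The five (unequally spaced) weeks at which body weight is recorded.
#' Correlation structures operate on the 0-based measurement position, not on
#' the week value, so the AR(1) lag between week 1 and week 7 is 1, not 6.
#'
#' @return Integer vector of week labels, strictly increasing.
#' @export
week_labels <- function() c(1L, 7L, 14L, 21L, 28L)

# Generating parameters, one row per arm x week:
# null mean (shared across arms), alternative mean, SEM, SD (all grams).
.table1_values <- function() {
  tibble::tribble(
    ~treatment,  ~week, ~mean_null, ~mean_alt,  ~sem,   ~sd,
    "HFol-HFol",    1L,       160,    166.45,   7.97,  27.57,
    "HFol-RV",      1L,       160,    165.27,   6.79,  23.48,
    "RV-RV",        1L,       160,    149.92,   6.00,  20.76,
    "HFol-HFol",    7L,       480,    478.77,   8.26,  28.59,
    "HFol-RV",      7L,       480,    492.34,  12.98,  44.92,
    "RV-RV",        7L,       480,    468.14,  11.21,  38.80,
    "HFol-HFol",   14L,       630,    615.83,  17.70,  61.26,
    "HFol-RV",     14L,       630,    654.19,  21.54,  74.53,
    "RV-RV",       14L,       630,    619.96,  15.34,  53.09,
    "HFol-HFol",   21L,       724,    697.41,  19.48,  67.38,
    "HFol-RV",     21L,       724,    752.89,  26.85,  92.91,
    "RV-RV",       21L,       724,    721.02,  16.23,  56.15,
    "HFol-HFol",   28L,       800,    764.83,  23.90,  82.70,
    "HFol-RV",     28L,       800,    835.06,  33.05, 114.35,
    "RV-RV",       28L,       800,    790.21,  15.64,  54.11
  )
}

#' Published simulation parameters
#'
#' Returns the 3 arm x 5 week table of generating parameters digitised from the
#' source mouse feeding trial: per-cell null-simulation mean, alternative-
#' simulation mean, SEM and SD, all in grams. Under the null model all arms
#' share a common mean at each week (160, 480, 630, 724, 800 g); SDs are
#' cell-specific in both hypotheses. The SD column equals SEM x sqrt(12)
#' (the donor study's group size) up to digitisation rounding; see
#' [sem_to_sd()].
#'
#' The same values ship as a plain-text fixture at
#' `system.file("extdata", "table1.csv", package = "rmasim")`.
#'
#' @return A tibble with columns `treatment`, `week`, `mean_null`, `mean_alt`,
#'   `sem`, `sd`; 15 rows ordered by week then arm.
#' @examples
#' param_table()
#' @export
param_table <- function() {
  tab <- .table1_values()
  tab$treatment <- factor(tab$treatment, levels = arm_labels())
  dplyr::arrange(tab, .data$week, .data$treatment)
}

#' Convert a standard error of the mean to a standard deviation
#'
#' `sd = sem * sqrt(n)`. The simulation parameter table was built with
#' `n = 12`, the per-group size of the donor study, regardless of the group
#' size later simulated.
#'
#' @param sem Standard error(s) of the mean, grams; non-negative.
#' @param n Sample size(s) behind the SEM; at least 1.
#' @return Standard deviation(s), grams.
#' @examples
#' sem_to_sd(7.97, 12) # ~27.6, matching the printed 27.57
#' @export
sem_to_sd <- function(sem, n) {
  if (any(sem < 0)) stop("`sem` must be non-negative")
  if (any(n < 1)) stop("`n` must be at least 1")
  sem * sqrt(n)
}

#' Define one simulation scenario
#'
#' A scenario fixes the generating covariance structure, the per-group sample
#' size, the within-subject correlation, and whether group means follow the
#' null (no treatment effect) or the alternative parameter set.
#'
#' @param truth Generating structure, `"het_cs"` (heterogeneous compound
#'   symmetry) or `"het_ar1"` (heterogeneous first-order autoregressive).
#' @param n_per_group Subjects per arm; the study grid uses 3, 6 or 12.
#' @param rho Within-subject correlation, in `[0, 1)`; grid values 0.1, 0.3,
#'   0.6, 0.9.
#' @param hypothesis `"null"` or `"alternative"`.
#' @param n_reps Number of Monte-Carlo replicates (default 1000).
#' @param base_seed Integer seed from which per-replicate seeds derive.
#' @param alpha Rejection level (default 0.05).
#' @return A list of class `"rma_scenario"`.
#' @examples
#' scenario("het_cs", n_per_group = 12, rho = 0.3, hypothesis = "null")
#' @export
scenario <- function(truth = c("het_cs", "het_ar1"),
                     n_per_group = 12,
                     rho = 0.3,
                     hypothesis = c("null", "alternative"),
                     n_reps = 1000,
                     base_seed = 20190801,
                     alpha = 0.05) {
  truth <- match.arg(truth)
  hypothesis <- match.arg(hypothesis)
  if (!is.numeric(rho) || length(rho) != 1 || rho < 0 || rho >= 1)
    stop("`rho` must be a single value in [0, 1)")
  if (n_per_group < 2) stop("`n_per_group` must be at least 2")
  if (n_reps < 1) stop("`n_reps` must be at least 1")
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must be in (0, 1)")
  structure(
    list(truth = truth, n_per_group = as.integer(n_per_group), rho = rho,
         hypothesis = hypothesis, n_reps = as.integer(n_reps),
         base_seed = as.integer(base_seed), alpha = alpha),
    class = "rma_scenario"
  )
}

#' @export
print.rma_scenario <- function(x, ...) {
  cat(sprintf(
    "<rma_scenario> %s truth, %s means, n = %d/group, rho = %.2f, %d reps (seed %d)\n",
    x$truth, x$hypothesis, x$n_per_group, x$rho, x$n_reps, x$base_seed))
  invisible(x)
}

#' Enumerate the full factorial scenario grid
#'
#' The study crosses 2 generating structures x 3 sample sizes x 4 correlations,
#' each simulated under both the null and the alternative model: 48 scenarios.
#' Each grid row carries a distinct derived seed so any scenario can be re-run
#' in isolation.
#'
#' @param n_reps Replicates per scenario (default 1000).
#' @param base_seed Base seed; per-scenario and per-replicate seeds derive from
#'   it (see [rep_seed()]).
#' @param alpha Rejection level.
#' @return A tibble with one row per scenario: `scenario_id`, `truth`,
#'   `hypothesis`, `n_per_group`, `rho`, `n_reps`, `base_seed`, `alpha`, and a
#'   list-column `scenario` of [scenario()] objects.
#' @examples
#' nrow(scenario_grid()) # 48
#' @export
scenario_grid <- function(n_reps = 1000, base_seed = 20190801, alpha = 0.05) {
  grid <- tidyr::expand_grid(
    truth = c("het_cs", "het_ar1"),
    hypothesis = c("null", "alternative"),
    n_per_group = c(3L, 6L, 12L),
    rho = c(0.1, 0.3, 0.6, 0.9)
  )
  grid <- dplyr::mutate(grid, scenario_id = dplyr::row_number(), .before = 1)
  grid$scenario <- purrr::pmap(
    grid[c("truth", "hypothesis", "n_per_group", "rho")],
    function(truth, hypothesis, n_per_group, rho) {
      scenario(truth, n_per_group, rho, hypothesis,
               n_reps = n_reps, base_seed = base_seed, alpha = alpha)
    }
  )
  grid$n_reps <- as.integer(n_reps)
  grid$base_seed <- as.integer(base_seed)
  grid$alpha <- alpha
  grid
}

# Position of a scenario in the canonical 48-row grid; used for seed
# derivation so identical scenarios get identical streams however created.
scenario_index <- function(sc) {
  truths <- c(het_cs = 0L, het_ar1 = 1L)
  hyps <- c(null = 0L, alternative = 1L)
  ns <- c(`3` = 0L, `6` = 1L, `12` = 2L)
  rhos <- c(`0.1` = 0L, `0.3` = 1L, `0.6` = 2L, `0.9` = 3L)
  rho_key <- format(sc$rho, trim = TRUE)
  if (!rho_key %in% names(rhos) || !as.character(sc$n_per_group) %in% names(ns)) {
    # off-grid scenarios hash to a stable slot beyond the canonical 48
    return(49L + (sc$n_per_group * 13L + as.integer(round(sc$rho * 1000))) %% 950L)
  }
  1L + truths[[sc$truth]] * 24L + hyps[[sc$hypothesis]] * 12L +
    ns[[as.character(sc$n_per_group)]] * 4L + rhos[[rho_key]]
}

#' Per-replicate random seed
#'
#' Deterministic counter-mode seed for one replicate of one scenario:
#' `base_seed + (scenario_slot - 1) * 1e6 + rep_index`. Injective across the
#' grid for `rep_index < 1e6`, stable across platforms and invocations, and
#' kept below 2^31.
#'
#' @param base_seed Integer base seed (0 to 2^31 - 1e9, guarded).
#' @param sc A [scenario()] object.
#' @param rep_index Replicate number, 1-based.
#' @return A single integer seed.
#' @export
rep_seed <- function(base_seed, sc, rep_index) {
  stopifnot(rep_index >= 1, rep_index < 1e6)
  base <- as.double(base_seed) %% (2^31 - 1.1e9)
  as.integer(base + (scenario_index(sc) - 1) * 1e6 + rep_index)
}
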