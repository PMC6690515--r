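#' Simulate one balanced repeated-measures dataset
#'
#' Draws, for each treatment arm, `n_per_group` independent subjects from a
#' multivariate normal whose mean vector is the arm's null or alternative
#' means (per the scenario's hypothesis) and whose covariance is the
#' scenario's structure built from that arm's per-week SDs and the scenario
#' `rho`. Groups share means under the null but always keep their own
#' extracted SDs, so each arm has its own generating covariance matrix.
#'
#' The draw is a pure function of `(base_seed, scenario, rep_index)`: the same
#' triple always reproduces the identical dataset.
#'
#' @param params Parameter table, as from [param_table()].
#' @param sc A [scenario()].
#' @param rep_index Replicate number, 1-based; must not exceed `sc$n_reps`.
#' @return A tibble in long format: `subject` (e.g. `"g1_s03"`), `treatment`
#'   (factor), `time_index` (1-based position), `week`, `response` (grams);
#'   `3 * n_per_group * 5` rows, every subject complete.
#' @examples
#' d <- simulate_dataset(param_table(), scenario("het_cs", 12, 0.3, "null"), 1)
#' nrow(d) # 180
#' @export
simulate_dataset <- function(params, sc, rep_index = 1) {
  stopifnot(inherits(sc, "rma_scenario"))
  if (rep_index > sc$n_reps) stop("`rep_index` exceeds the scenario's `n_reps`")
  arms <- arm_labels()
  weeks <- week_labels()
  n_t <- length(weeks)
  mean_col <- if (sc$hypothesis == "null") "mean_null" else "mean_alt"
  set.seed(rep_seed(sc$base_seed, sc, rep_index))
  out <- purrr::imap(arms, function(arm, g) {
    mu <- params[[mean_col]][params$treatment == arm]
    sigma <- arm_covariance(params, arm, sc)
    y <- MASS::mvrnorm(sc$n_per_group, mu = mu, Sigma = sigma)
    y <- matrix(y, nrow = sc$n_per_group) # mvrnorm drops dim when n = 1
    tibble::tibble(
      subject = rep(sprintf("g%d_s%02d", g, seq_len(sc$n_per_group)),
                    each = n_t),
      treatment = arm,
      time_index = rep(seq_len(n_t), sc$n_per_group),
      week = rep(weeks, sc$n_per_group),
      response = as.vector(t(y))
    )
  })
  out <- dplyr::bind_rows(out)
  out$treatment <- factor(out$treatment, levels = arms)
  out
}

#' Write / read a long-format dataset as CSV
#'
#' Header `subject,treatment,week,response`; lossless at full double
#' precision. `read_long_csv()` restores the `time_index` column from the week
#' ordering.
#'
#' @param data A long-format dataset, as from [simulate_dataset()].
#' @param path File path.
#' @return `write_long_csv()` returns `path` invisibly; `read_long_csv()`
#'   returns the dataset tibble.
#' @export
write_long_csv <- function(data, path) {
  readr::write_csv(data[c("subject", "treatment", "week", "response")], path)
  invisible(path)
}

#' @rdname write_long_csv
#' @export
read_long_csv <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("subject", "treatment", "week", "response")
  if (!all(need %in% names(d)))
    stop("CSV must have columns ", paste(need, collapse = ", "))
  d$subject <- as.character(d$subject)
  d$week <- as.integer(d$week)
  d$response <- as.double(d$response)
  weeks <- sort(unique(d$week))
  d$time_index <- match(d$week, weeks)
  d$treatment <- factor(d$treatment)
  dplyr::select(d, "subject", "treatment", "time_index", "week", "response")
}

# Validates balance/completeness and reshapes to an N x T response matrix
# plus per-subject group labels; fits key on (subject, treatment, time_index),
# never on row order.
as_balanced_matrix <- function(data) {
  need <- c("subject", "treatment", "time_index", "response")
  if (!all(need %in% names(data)))
    stop("data must have columns ", paste(need, collapse = ", "))
  d <- dplyr::arrange(data, .data$subject, .data$time_index)
  times <- sort(unique(d$time_index))
  n_t <- length(times)
  counts <- table(d$subject, d$time_index)
  if (any(counts != 1))
    stop("data must be balanced and complete: every subject needs exactly one row per time point")
  if (any(tapply(d$treatment, d$subject, function(g) length(unique(g))) != 1))
    stop("each subject must belong to exactly one treatment arm")
  subjects <- unique(d$subject)
  y <- matrix(d$response, nrow = length(subjects), ncol = n_t, byrow = TRUE)
  grp <- d$treatment[match(subjects, d$subject)]
  grp <- droplevels(factor(grp))
  if (nlevels(grp) < 2) stop("need at least two treatment arms")
  if (any(table(grp) < 2)) stop("need at least two subjects per arm")
  list(y = y, group = grp, subjects = subjects, n_time = n_t,
       weeks = sort(unique(data$week)))
}
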