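# Wald F tests on the cell-means parameterization. beta is laid out
# group-major: (g1 w1..wT, g2 w1..wT, ...).

beta_index <- function(g, t, n_time) (g - 1) * n_time + t

# contrast matrices (rows = df) for the standard repeated-measures tests
contrast_matrix <- function(which, n_groups, n_time) {
  p <- n_groups * n_time
  rows <- switch(
    which,
    treatment = lapply(seq_len(n_groups - 1), function(g) {
      l <- numeric(p)
      l[beta_index(g, seq_len(n_time), n_time)] <- 1 / n_time
      l[beta_index(n_groups, seq_len(n_time), n_time)] <- -1 / n_time
      l
    }),
    time = lapply(seq_len(n_time - 1), function(t) {
      l <- numeric(p)
      l[beta_index(seq_len(n_groups), t, n_time)] <- 1 / n_groups
      l[beta_index(seq_len(n_groups), n_time, n_time)] <-
        l[beta_index(seq_len(n_groups), n_time, n_time)] - 1 / n_groups
      l
    }),
    interaction = unlist(lapply(seq_len(n_groups - 1), function(g) {
      lapply(seq_len(n_time - 1), function(t) {
        l <- numeric(p)
        l[beta_index(g, t, n_time)] <- 1
        l[beta_index(g, n_time, n_time)] <- -1
        l[beta_index(n_groups, t, n_time)] <- -1
        l[beta_index(n_groups, n_time, n_time)] <- 1
        l
      })
    }), recursive = FALSE),
    stop("unknown contrast set: ", which)
  )
  do.call(rbind, rows)
}

time_contrast_matrix <- function(time_index, n_groups, n_time) {
  p <- n_groups * n_time
  do.call(rbind, lapply(seq_len(n_groups - 1), function(g) {
    l <- numeric(p)
    l[beta_index(g, time_index, n_time)] <- 1
    l[beta_index(n_groups, time_index, n_time)] <- -1
    l
  }))
}

# Satterthwaite denominator df for the Wald F of contrast L, following the
# eigenvector decomposition used for multi-df contrasts in mixed models:
# each 1-df direction gets nu_m = 2 c_m^2 / Var(c_m), variances from the
# delta method with the observed information of the covariance parameters.
satterthwaite_ddf <- function(fit, L) {
  if (is.null(fit$theta_vcov)) return(NA_real_)
  C <- L %*% fit$fixed_vcov %*% t(L)
  q <- nrow(L)
  derivs <- sigma_derivs(fit$theta, fit$kind, fit$n_time)
  dV <- lapply(derivs, function(d) kronecker(diag(1 / fit$n_per_group), d))
  if (q == 1) {
    g <- vapply(dV, function(dv) drop(L %*% dv %*% t(L)), numeric(1))
    var_c <- drop(t(g) %*% fit$theta_vcov %*% g)
    if (var_c <= 0) return(NA_real_)
    return(2 * drop(C)^2 / var_c)
  }
  e <- eigen(C, symmetric = TRUE)
  nu <- vapply(seq_len(q), function(m) {
    b <- e$vectors[, m]
    lb <- drop(t(b) %*% L)
    g <- vapply(dV, function(dv) drop(t(lb) %*% dv %*% lb), numeric(1))
    var_c <- drop(t(g) %*% fit$theta_vcov %*% g)
    if (var_c <= 0) return(Inf)
    2 * e$values[m]^2 / var_c
  }, numeric(1))
  contrib <- nu[nu > 2] / (nu[nu > 2] - 2)
  E <- sum(contrib)
  if (length(contrib) < q || E <= q) return(NA_real_)
  2 * E / (E - q)
}

# df fallback chain: satterthwaite -> between-within -> residual
resolve_ddf <- function(fit, L, method, within) {
  n_resid <- fit$n_subjects * fit$n_time - fit$n_groups * fit$n_time
  bw <- if (within) {
    (fit$n_subjects - fit$n_groups) * (fit$n_time - 1)
  } else {
    fit$n_subjects - fit$n_groups
  }
  if (method == "residual") return(n_resid)
  if (method == "between-within") return(bw)
  d <- satterthwaite_ddf(fit, L)
  if (!is.finite(d) || d <= 0) bw else d
}

wald_test <- function(fit, L, method, within) {
  beta <- as.vector(t(fit$cell_means))
  est <- drop(L %*% beta)
  C <- L %*% fit$fixed_vcov %*% t(L)
  q <- nrow(L)
  Fstat <- drop(t(est) %*% solve(C, est)) / q
  ddf <- resolve_ddf(fit, L, method, within)
  tibble::tibble(
    statistic = Fstat, df_num = q, df_den = ddf,
    p_value = stats::pf(Fstat, q, ddf, lower.tail = FALSE)
  )
}

#' Overall Wald F tests for a repeated-measures fit
#'
#' Tests the treatment main effect (G-1 df), time main effect (T-1 df) and
#' treatment-by-time interaction ((G-1)(T-1) df) via Wald F statistics on the
#' cell means, using the fitted residual covariance.
#'
#' @param fit An [fit_gls_reml()] object (converged).
#' @param ddf Denominator df method; defaults to the fit's setting.
#'   `"satterthwaite"` uses the delta-method eigenvector approximation;
#'   `"residual"` uses `N*T - G*T`; `"between-within"` partitions subject and
#'   within-subject df.
#' @return A tibble with one row per effect: `effect`, `statistic`, `df_num`,
#'   `df_den`, `p_value`.
#' @examples
#' d <- simulate_dataset(param_table(), scenario("het_cs", 6, 0.3, "null"), 1)
#' test_fixed_effects(fit_gls_reml(d, "het_cs"))
#' @export
test_fixed_effects <- function(fit, ddf = NULL) {
  stopifnot(inherits(fit, "rma_fit"))
  if (!fit$converged) warning("fit did not converge; tests may be unreliable")
  method <- if (is.null(ddf)) fit$ddf else
    match.arg(ddf, c("satterthwaite", "residual", "between-within"))
  effects <- c("treatment", "time", "interaction")
  out <- purrr::map(effects, function(e) {
    L <- contrast_matrix(e, fit$n_groups, fit$n_time)
    wald_test(fit, L, method, within = e != "treatment")
  })
  dplyr::bind_cols(tibble::tibble(effect = effects), dplyr::bind_rows(out))
}

#' Treatment contrast at a single time point
#'
#' The per-week "treatment effect" of the repeated-measures analysis: a joint
#' (G-1)-df Wald F for equality of all arm means at one time point, plus the
#' standard error for comparing two treatment means (SEM) for every arm pair
#' at that time, read off the fixed-effect covariance. Under a pooled
#' residual structure with equal group sizes the pairwise SEM is
#' `sqrt(2 * sigma_t^2 / n)`, so homogeneous structures force it constant
#' across weeks while heterogeneous ones track the per-week variance.
#'
#' @param fit An [fit_gls_reml()] object.
#' @param time_index Time-point position, 1-based.
#' @param ddf Denominator df method; defaults to the fit's setting.
#' @return A one-row tibble: `time_index`, `week`, `statistic`, `df_num`,
#'   `df_den`, `p_value`, plus a list-column `pairwise` holding a tibble of
#'   per-pair differences, SEMs and t tests.
#' @examples
#' d <- simulate_dataset(param_table(), scenario("het_cs", 6, 0.3, "null"), 1)
#' time_point_contrast(fit_gls_reml(d, "het_cs"), 5)
#' @export
time_point_contrast <- function(fit, time_index, ddf = NULL) {
  stopifnot(inherits(fit, "rma_fit"))
  if (time_index < 1 || time_index > fit$n_time)
    stop("`time_index` out of range")
  method <- if (is.null(ddf)) fit$ddf else
    match.arg(ddf, c("satterthwaite", "residual", "between-within"))
  L <- time_contrast_matrix(time_index, fit$n_groups, fit$n_time)
  joint <- wald_test(fit, L, method, within = FALSE)

  pairs <- utils::combn(fit$n_groups, 2)
  beta <- as.vector(t(fit$cell_means))
  pw <- purrr::map(seq_len(ncol(pairs)), function(k) {
    g1 <- pairs[1, k]; g2 <- pairs[2, k]
    l <- matrix(0, 1, fit$n_groups * fit$n_time)
    l[1, beta_index(g1, time_index, fit$n_time)] <- 1
    l[1, beta_index(g2, time_index, fit$n_time)] <- -1
    sem <- sqrt(drop(l %*% fit$fixed_vcov %*% t(l)))
    tt <- wald_test(fit, l, method, within = FALSE)
    tibble::tibble(
      pair = paste(fit$groups[g1], fit$groups[g2], sep = " vs "),
      difference = drop(l %*% beta), sem = sem,
      statistic = sign(difference) * sqrt(tt$statistic),
      df = tt$df_den, p_value = tt$p_value
    )
  })
  dplyr::bind_cols(
    tibble::tibble(time_index = as.integer(time_index),
                   week = fit$weeks[time_index]),
    joint,
    tibble::tibble(pairwise = list(dplyr::bind_rows(pw)))
  )
}
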