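# Core REML machinery for the saturated cell-means model on balanced data.
#
# With a saturated treatment x time mean structure and complete balanced
# data, GLS cell means equal per-cell sample means for ANY residual
# covariance, so the restricted likelihood profiles down to a function of
# the T x T within-subject covariance alone:
#
#   l_R(Sigma) = -1/2 [ (N - G) log|Sigma| + tr(Sigma^-1 S)
#                       + T * sum_g log n_g + (N - G) T log(2*pi) ]
#
# where S is the sum over subjects of residual outer products about their
# own cell means, N subjects in G groups. The fixed-effect covariance is
# block-diagonal: Var(mean_g) = Sigma / n_g.

# sufficient statistics for the profiled criterion
reml_suffstats <- function(bm) {
  g_levels <- levels(bm$group)
  n_g <- as.integer(table(bm$group))
  means <- t(vapply(g_levels, function(g) colMeans(bm$y[bm$group == g, , drop = FALSE]),
                    numeric(bm$n_time)))
  resid <- bm$y - means[as.integer(bm$group), , drop = FALSE]
  list(S = crossprod(resid), means = means, n_g = n_g,
       N = nrow(bm$y), G = length(g_levels), n_time = bm$n_time,
       g_levels = g_levels, weeks = bm$weeks)
}

reml_loglik_sigma <- function(sigma, ss) {
  ch <- tryCatch(chol(sigma), error = function(e) NULL)
  if (is.null(ch)) return(-Inf)
  logdet <- 2 * sum(log(diag(ch)))
  quad <- sum(diag(chol2inv(ch) %*% ss$S))
  nmg <- ss$N - ss$G
  -0.5 * (nmg * logdet + quad + ss$n_time * sum(log(ss$n_g)) +
            nmg * ss$n_time * log(2 * pi))
}

#' Restricted log-likelihood of a trial covariance structure
#'
#' Evaluates the REML criterion of the saturated treatment x time cell-means
#' model at a given residual covariance, with the fixed effects profiled out.
#' Requires balanced complete data; each subject contributes one T x T block.
#'
#' @param data Long-format balanced dataset (see [simulate_dataset()]).
#' @param spec A [cov_spec()] with trial parameter values.
#' @return The restricted log-likelihood (a single number; `-Inf` if the trial
#'   covariance is singular).
#' @export
reml_criterion <- function(data, spec) {
  bm <- as_balanced_matrix(data)
  ss <- reml_suffstats(bm)
  if (ss$N == ss$G || sum(diag(ss$S)) <= 0)
    stop("degenerate data: no within-group residual variation")
  ll <- reml_loglik_sigma(build_covariance(spec, ss$n_time), ss)
  if (!is.finite(ll)) stop("trial covariance is singular")
  ll
}

# --- parameter mappings -----------------------------------------------------
# Natural parameters theta: variances then rho.
#   het kinds: (v_1, ..., v_T, rho);  hom kinds: (v, rho)
# Fitting runs on an unconstrained scale: log v, and a scaled logit carrying
# rho onto (-1/(T-1), 1) for CS (positive definiteness bound at T points) or
# (-1, 1) for AR(1).

rho_lower <- function(kind, n_time) {
  if (kind %in% c("het_cs", "hom_cs")) -1 / (n_time - 1) else -1
}

theta_to_sigma <- function(theta, kind, n_time) {
  if (kind %in% c("het_cs", "het_ar1")) {
    v <- theta[seq_len(n_time)]; rho <- theta[n_time + 1]
  } else {
    v <- rep(theta[1], n_time); rho <- theta[2]
  }
  sig <- sqrt(v)
  lag <- abs(outer(seq_len(n_time), seq_len(n_time), "-"))
  r <- if (kind %in% c("het_cs", "hom_cs")) ifelse(lag == 0, 1, rho) else rho^lag
  outer(sig, sig) * r
}

unconstrained_to_theta <- function(u, kind, n_time) {
  lo <- rho_lower(kind, n_time)
  p <- length(u)
  rho <- lo + (1 - lo) * stats::plogis(u[p])
  c(exp(u[-p]), rho)
}

theta_to_unconstrained <- function(theta, kind, n_time) {
  lo <- rho_lower(kind, n_time)
  p <- length(theta)
  z <- stats::qlogis(pmin(pmax((theta[p] - lo) / (1 - lo), 1e-8), 1 - 1e-8))
  c(log(theta[-p]), z)
}

# analytic d(Sigma)/d(theta_k) at natural parameters
sigma_derivs <- function(theta, kind, n_time) {
  het <- kind %in% c("het_cs", "het_ar1")
  v <- if (het) theta[seq_len(n_time)] else rep(theta[1], n_time)
  rho <- theta[length(theta)]
  sig <- sqrt(v)
  lag <- abs(outer(seq_len(n_time), seq_len(n_time), "-"))
  cs <- kind %in% c("het_cs", "hom_cs")
  r <- if (cs) ifelse(lag == 0, 1, rho) else rho^lag
  derivs <- list()
  if (het) {
    for (t in seq_len(n_time)) {
      d <- matrix(0, n_time, n_time)
      # d(sig_i sig_j r_ij)/d v_t = r_ij * sig_j / (2 sig_t) for i = t
      d[t, ] <- r[t, ] * sig / (2 * sig[t])
      d[, t] <- d[t, ]
      d[t, t] <- 1
      derivs[[t]] <- d
    }
  } else {
    derivs[[1]] <- r # Sigma = v * R
  }
  drho <- if (cs) {
    ifelse(lag == 0, 0, 1) * outer(sig, sig)
  } else {
    dr <- ifelse(lag == 0, 0, lag * rho^pmax(lag - 1, 0))
    dr * outer(sig, sig)
  }
  c(derivs, list(drho))
}

# deterministic jitter factors for optimizer restarts
.restart_scales <- list(c(1, 1), c(1.25, 0.5), c(0.8, 1.5), c(1.6, 0.25))

fit_structured <- function(ss, kind) {
  n_time <- ss$n_time
  pooled <- ss$S / (ss$N - ss$G)
  corr <- stats::cov2cor(pooled)
  lag1 <- mean(corr[cbind(seq_len(n_time - 1), seq_len(n_time - 1) + 1)])
  lo <- rho_lower(kind, n_time)
  rho0 <- min(max(lag1, lo + 0.05), 0.95)
  v0 <- if (kind %in% c("het_cs", "het_ar1")) diag(pooled) else mean(diag(pooled))
  negll <- function(u) {
    th <- unconstrained_to_theta(u, kind, n_time)
    -reml_loglik_sigma(theta_to_sigma(th, kind, n_time), ss)
  }
  best <- NULL
  n_iter <- 0L
  for (rs in .restart_scales) {
    th0 <- c(v0 * rs[1], lo + (rho0 - lo) * rs[2] + 0)
    u0 <- theta_to_unconstrained(th0, kind, n_time)
    opt <- tryCatch(
      stats::optim(u0, negll, method = "BFGS",
                   control = list(maxit = 300, reltol = 1e-12)),
      error = function(e) NULL)
    if (is.null(opt)) next
    n_iter <- n_iter + opt$counts[["function"]]
    g <- tryCatch(pracma::grad(negll, opt$par), error = function(e) rep(Inf, length(u0)))
    ok <- opt$convergence == 0 &&
      sqrt(sum(g^2)) < 1e-5 * max(1, abs(opt$value))
    if (is.null(best) || opt$value < best$value) {
      best <- list(value = opt$value, par = opt$par, ok = ok)
    }
    if (ok) { best <- list(value = opt$value, par = opt$par, ok = TRUE); break }
  }
  theta <- unconstrained_to_theta(best$par, kind, n_time)
  list(theta = theta, loglik = -best$value, converged = isTRUE(best$ok),
       n_iter = n_iter)
}

#' Fit the cell-means repeated-measures model by REML
#'
#' Estimates the residual covariance parameters of the requested structure by
#' maximising the profiled restricted likelihood (quasi-Newton on an
#' unconstrained scale: log variances, scaled-logit correlation), with the
#' saturated treatment x time fixed effects recovered in closed form as the
#' per-cell sample means. One pooled covariance is assumed for all subjects,
#' the usual repeated-measures formulation. The `"unstructured"` kind has a
#' closed-form optimum, the pooled within-group sample covariance with divisor
#' `N - G`.
#'
#' @param data Long-format balanced dataset with columns `subject`,
#'   `treatment`, `time_index`, `response` (and optionally `week`).
#' @param kind Covariance structure: `"het_cs"`, `"het_ar1"`, `"hom_cs"`,
#'   `"hom_ar1"` or `"unstructured"`.
#' @param ddf Default denominator-degrees-of-freedom method for tests on this
#'   fit: `"satterthwaite"` (default), `"residual"` or `"between-within"`.
#' @return An object of class `"rma_fit"`: cell means, estimated covariance
#'   (`sigma`, and `cov_params` as a [cov_spec()]), fixed-effect covariance,
#'   REML log-likelihood, convergence flag. Non-convergence after three
#'   jittered restarts is reported via `converged = FALSE`, not an error.
#' @examples
#' d <- simulate_dataset(param_table(), scenario("het_cs", 6, 0.3, "null"), 1)
#' fit <- fit_gls_reml(d, "het_cs")
#' glance(fit)
#' @export
fit_gls_reml <- function(data, kind = c("het_cs", "het_ar1", "hom_cs",
                                        "hom_ar1", "unstructured"),
                         ddf = c("satterthwaite", "residual", "between-within")) {
  kind <- match.arg(kind)
  ddf <- match.arg(ddf)
  bm <- as_balanced_matrix(data)
  ss <- reml_suffstats(bm)
  if (sum(diag(ss$S)) <= 0)
    stop("degenerate data: no within-group residual variation")
  n_time <- ss$n_time

  if (kind == "unstructured") {
    sigma <- ss$S / (ss$N - ss$G)
    if (!is_positive_definite(sigma))
      stop("pooled within-group covariance is singular; need more subjects than time points")
    est <- list(theta = NULL, loglik = reml_loglik_sigma(sigma, ss),
                converged = TRUE, n_iter = 0L)
    spec <- cov_spec("unstructured", free_matrix = sigma)
    theta_vcov <- NULL
  } else {
    est <- fit_structured(ss, kind)
    sigma <- theta_to_sigma(est$theta, kind, n_time)
    # constructed directly: a fitted rho may sit slightly below 0, outside
    # the [0, 1) range cov_spec() enforces for user-specified structures
    spec <- if (kind %in% c("het_cs", "het_ar1")) {
      structure(list(kind = kind, sigmas = sqrt(est$theta[seq_len(n_time)]),
                     sigma2 = NULL, rho = est$theta[n_time + 1],
                     free_matrix = NULL), class = "cov_spec")
    } else {
      structure(list(kind = kind, sigmas = NULL, sigma2 = est$theta[1],
                     rho = est$theta[2], free_matrix = NULL),
                class = "cov_spec")
    }
    # expected REML information at the optimum, natural scale:
    # I_kl = (N - G)/2 * tr(Sigma^-1 dSigma_k Sigma^-1 dSigma_l)
    theta_vcov <- tryCatch({
      derivs <- sigma_derivs(est$theta, kind, n_time)
      si <- solve(sigma)
      sd_list <- lapply(derivs, function(d) si %*% d)
      p <- length(derivs)
      info <- matrix(0, p, p)
      for (k in seq_len(p)) for (l in k:p) {
        info[k, l] <- info[l, k] <-
          0.5 * (ss$N - ss$G) * sum(sd_list[[k]] * t(sd_list[[l]]))
      }
      a <- solve(info)
      if (any(!is.finite(a)) || any(diag(a) <= 0)) NULL else a
    }, error = function(e) NULL)
  }

  fixed_vcov <- kronecker(diag(1 / ss$n_g), sigma)
  beta_names <- as.vector(t(outer(ss$g_levels, ss$weeks,
                                  function(g, w) paste0(g, ":week", w))))
  dimnames(fixed_vcov) <- list(beta_names, beta_names)
  cm <- ss$means
  dimnames(cm) <- list(ss$g_levels, paste0("week", ss$weeks))

  structure(list(
    kind = kind, cell_means = cm, cov_params = spec, sigma = sigma,
    theta = est$theta, theta_vcov = theta_vcov,
    fixed_vcov = fixed_vcov, reml_loglik = est$loglik,
    converged = est$converged, n_iter = est$n_iter,
    n_subjects = ss$N, n_groups = ss$G, n_per_group = ss$n_g,
    n_time = n_time, weeks = ss$weeks, groups = ss$g_levels,
    ddf = ddf
  ), class = "rma_fit")
}

#' @export
print.rma_fit <- function(x, ...) {
  cat(sprintf("<rma_fit> %s structure, REML logLik %.3f (%s)\n",
              x$kind, x$reml_loglik,
              if (x$converged) "converged" else "NOT converged"))
  cat("cell means (g):\n")
  print(round(x$cell_means, 2))
  if (!is.null(x$theta)) {
    p <- length(x$theta)
    cat(sprintf("rho-hat = %.4f; ", x$theta[p]))
    cat("variance estimates:", paste(round(x$theta[-p], 2), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Tidy a repeated-measures fit
#'
#' @param x An [fit_gls_reml()] object.
#' @param ... Unused.
#' @return A tibble of estimated cell means with standard errors: one row per
#'   treatment x week, columns `treatment`, `week`, `estimate`, `std_error`.
#' @importFrom generics tidy
#' @method tidy rma_fit
#' @export
tidy.rma_fit <- function(x, ...) {
  se <- sqrt(diag(x$fixed_vcov))
  tibble::tibble(
    treatment = rep(x$groups, each = x$n_time),
    week = rep(x$weeks, times = x$n_groups),
    estimate = as.vector(t(x$cell_means)),
    std_error = se
  )
}

#' Glance at a repeated-measures fit
#'
#' @param x An [fit_gls_reml()] object.
#' @param ... Unused.
#' @return A one-row tibble: structure kind, REML log-likelihood, estimated
#'   correlation, convergence flag, subject counts.
#' @importFrom generics glance
#' @method glance rma_fit
#' @export
glance.rma_fit <- function(x, ...) {
  rho <- if (is.null(x$theta)) NA_real_ else x$theta[length(x$theta)]
  tibble::tibble(
    kind = x$kind, reml_loglik = x$reml_loglik, rho = rho,
    converged = x$converged, n_subjects = x$n_subjects,
    n_groups = x$n_groups, n_time = x$n_time
  )
}
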