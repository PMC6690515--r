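#' Residual covariance structure specification
#'
#' Describes one of the residual covariance structures used for generating or
#' fitting: heterogeneous compound symmetry (`het_cs`), heterogeneous AR(1)
#' (`het_ar1`), their homogeneous (constant-variance) counterparts (`hom_cs`,
#' `hom_ar1`), or a fully unstructured matrix. Heterogeneous kinds carry one
#' positive SD per time point; homogeneous kinds a single common variance.
#' `rho` is restricted to `[0, 1)`, the range exercised by the simulation
#' grid.
#'
#' @param kind One of `"het_cs"`, `"het_ar1"`, `"hom_cs"`, `"hom_ar1"`,
#'   `"unstructured"`.
#' @param sigmas Per-time SDs (heterogeneous kinds only), grams.
#' @param sigma2 Common variance (homogeneous kinds only), grams^2.
#' @param rho Within-subject correlation, `[0, 1)` (structured kinds).
#' @param free_matrix Full symmetric covariance (unstructured only), grams^2.
#' @return A list of class `"cov_spec"`.
#' @examples
#' cov_spec("het_cs", sigmas = c(20, 30, 60, 65, 80), rho = 0.3)
#' cov_spec("hom_ar1", sigma2 = 400, rho = 0.5)
#' @export
cov_spec <- function(kind = c("het_cs", "het_ar1", "hom_cs", "hom_ar1",
                              "unstructured"),
                     sigmas = NULL, sigma2 = NULL, rho = NULL,
                     free_matrix = NULL) {
  kind <- match.arg(kind)
  if (kind %in% c("het_cs", "het_ar1")) {
    if (is.null(sigmas) || any(sigmas <= 0))
      stop("heterogeneous kinds need positive per-time `sigmas`")
    if (!is.null(sigma2)) stop("`sigma2` is not a parameter of ", kind)
  }
  if (kind %in% c("hom_cs", "hom_ar1")) {
    if (is.null(sigma2) || length(sigma2) != 1 || sigma2 <= 0)
      stop("homogeneous kinds need a single positive `sigma2`")
    if (!is.null(sigmas)) stop("`sigmas` is not a parameter of ", kind)
  }
  if (kind != "unstructured") {
    if (is.null(rho) || length(rho) != 1 || rho < 0 || rho >= 1)
      stop("`rho` must be a single value in [0, 1)")
  } else {
    if (is.null(free_matrix)) stop("unstructured kind needs `free_matrix`")
    if (!isSymmetric(unname(free_matrix), tol = 1e-8))
      stop("`free_matrix` must be symmetric")
  }
  structure(list(kind = kind, sigmas = sigmas, sigma2 = sigma2, rho = rho,
                 free_matrix = free_matrix),
            class = "cov_spec")
}

#' Realise a covariance specification as a T x T matrix
#'
#' Diagonal entries are `sigma_i^2` (heterogeneous) or the common `sigma^2`
#' (homogeneous). Off-diagonals are `sigma_i sigma_j rho` for compound
#' symmetry and `sigma_i sigma_j rho^|j - i|` for AR(1), where the lag is the
#' 0-based measurement position difference, not the week difference.
#'
#' @param spec A [cov_spec()].
#' @param n_time Number of time points `T`; must match the spec's dimensions.
#' @return A `T x T` symmetric positive-definite matrix, grams^2.
#' @examples
#' build_covariance(cov_spec("hom_ar1", sigma2 = 1, rho = 0.5), n_time = 3)
#' @export
build_covariance <- function(spec, n_time) {
  stopifnot(inherits(spec, "cov_spec"))
  if (spec$kind == "unstructured") {
    m <- spec$free_matrix
    if (nrow(m) != n_time) stop("`free_matrix` dimension does not match `n_time`")
    return(unname(m))
  }
  het <- spec$kind %in% c("het_cs", "het_ar1")
  sig <- if (het) spec$sigmas else rep(sqrt(spec$sigma2), n_time)
  if (length(sig) != n_time)
    stop("`sigmas` length does not match `n_time`")
  lag <- abs(outer(seq_len(n_time), seq_len(n_time), "-"))
  r <- if (spec$kind %in% c("het_cs", "hom_cs")) {
    ifelse(lag == 0, 1, spec$rho)
  } else {
    spec$rho^lag
  }
  m <- outer(sig, sig) * r
  if (!is_positive_definite(m))
    stop("resulting covariance matrix is not positive definite")
  m
}

#' Check positive definiteness
#'
#' A matrix passes when its smallest eigenvalue exceeds
#' `1e-10 * max(diag)`, a scale-relative tolerance.
#'
#' @param m Square symmetric matrix.
#' @return `TRUE` or `FALSE`.
#' @export
is_positive_definite <- function(m) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) stop("`m` must be square")
  if (!isSymmetric(unname(m), tol = 1e-8)) stop("`m` must be symmetric")
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  min(ev) > 1e-10 * max(diag(m))
}

# Generating covariance for one arm: that arm's Table-1 SD column with the
# scenario's structure and rho. Group-specific scale, common correlation.
arm_covariance <- function(params, arm, sc) {
  sig <- params$sd[params$treatment == arm]
  build_covariance(cov_spec(sc$truth, sigmas = sig, rho = sc$rho),
                   n_time = length(sig))
}
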