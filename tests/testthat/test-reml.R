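test_that("GLS cell means equal arithmetic group means on balanced data", {
  d <- fixture_dataset(4, n_per_group = 6)
  for (kind in c("het_cs", "hom_ar1", "unstructured")) {
    fit <- fit_gls_reml(d, kind)
    direct <- d |>
      dplyr::group_by(treatment, week) |>
      dplyr::summarise(m = mean(response), .groups = "drop") |>
      dplyr::arrange(treatment, week)
    expect_equal(as.vector(t(fit$cell_means)), direct$m, tolerance = 1e-8)
  }
})

test_that("the unstructured REML optimum is the pooled within-group covariance", {
  d <- fixture_dataset(5, n_per_group = 6)
  fit <- fit_gls_reml(d, "unstructured")
  # independent oracle: pool the per-arm centred outer products, divisor N - G
  wide <- tidyr::pivot_wider(d[c("subject", "treatment", "time_index", "response")],
                             names_from = "time_index", values_from = "response")
  y <- as.matrix(wide[, -(1:2)])
  resid <- do.call(rbind, lapply(split(as.data.frame(y), wide$treatment),
                                 function(g) scale(as.matrix(g), scale = FALSE)))
  pooled <- crossprod(resid) / (nrow(y) - length(unique(wide$treatment)))
  expect_equal(unname(fit$sigma), unname(pooled), tolerance = 1e-10)

  # local perturbations never improve the criterion
  base <- reml_criterion(d, cov_spec("unstructured", free_matrix = pooled))
  expect_equal(base, fit$reml_loglik, tolerance = 1e-6)
  set.seed(42)
  for (i in 1:10) {
    e <- matrix(stats::rnorm(25, sd = 2), 5); e <- (e + t(e)) / 2
    pert <- reml_criterion(d, cov_spec("unstructured", free_matrix = pooled + e))
    expect_lte(pert, base + 1e-6)
  }
})

test_that("heterogeneous criterion at equal sigmas equals the homogeneous one", {
  d <- fixture_dataset(6, n_per_group = 3)
  het <- reml_criterion(d, cov_spec("het_cs", sigmas = rep(30, 5), rho = 0.4))
  hom <- reml_criterion(d, cov_spec("hom_cs", sigma2 = 900, rho = 0.4))
  expect_equal(het, hom)
})

test_that("optimized criterion dominates the generating parameters and nests submodels", {
  params <- fixture_params
  for (r in 1:5) {
    sc <- fixture_scenario("null", n_reps = 10)
    d <- simulate_dataset(params, sc, r)
    f_het <- fit_gls_reml(d, "het_cs")
    f_hom <- fit_gls_reml(d, "hom_cs")
    f_un <- fit_gls_reml(d, "unstructured")
    # truth uses group-specific scales; the pooled fit must still beat the
    # pooled-average generating structure
    gen_sigmas <- sqrt(rowMeans(sapply(arm_labels(), function(a)
      params$sd[params$treatment == a]^2)))
    at_gen <- reml_criterion(d, cov_spec("het_cs", sigmas = gen_sigmas, rho = 0.3))
    expect_gte(f_het$reml_loglik, at_gen - 1e-8)
    expect_gte(f_het$reml_loglik, f_hom$reml_loglik - 1e-6)
    expect_gte(f_un$reml_loglik, f_het$reml_loglik - 1e-6)
    expect_true(f_het$converged && f_hom$converged)
  }
})

test_that("fits agree with the generalized least squares oracle (nlme::gls)", {
  skip_if_not_installed("nlme")
  d <- fixture_dataset(2)
  d$timef <- factor(d$time_index)

  fit <- fit_gls_reml(d, "het_cs")
  g <- nlme::gls(response ~ treatment:timef - 1, data = d,
                 correlation = nlme::corCompSymm(form = ~ 1 | subject),
                 weights = nlme::varIdent(form = ~ 1 | timef), method = "REML")
  expect_equal(fit$reml_loglik, as.numeric(stats::logLik(g)), tolerance = 1e-6)
  expect_equal(fit$theta[6],
               as.numeric(stats::coef(g$modelStruct$corStruct,
                                      unconstrained = FALSE)),
               tolerance = 1e-4)
  vw <- stats::coef(g$modelStruct$varStruct, unconstrained = FALSE,
                    allCoef = TRUE)
  expect_equal(sqrt(fit$theta[1:5]),
               unname(g$sigma * vw[as.character(1:5)]), tolerance = 1e-3)

  fit_h <- fit_gls_reml(d, "hom_cs")
  gh <- nlme::gls(response ~ treatment:timef - 1, data = d,
                  correlation = nlme::corCompSymm(form = ~ 1 | subject),
                  method = "REML")
  expect_equal(fit_h$reml_loglik, as.numeric(stats::logLik(gh)), tolerance = 1e-6)
  expect_equal(fit_h$theta[1], gh$sigma^2, tolerance = 1e-4)

  dA <- fixture_dataset(3, truth = "het_ar1", rho = 0.6)
  dA$timef <- factor(dA$time_index)
  fa <- fit_gls_reml(dA, "het_ar1")
  ga <- nlme::gls(response ~ treatment:timef - 1, data = dA,
                  correlation = nlme::corAR1(form = ~ time_index | subject),
                  weights = nlme::varIdent(form = ~ 1 | timef), method = "REML")
  expect_equal(fa$reml_loglik, as.numeric(stats::logLik(ga)), tolerance = 1e-6)
  expect_equal(fa$theta[6],
               as.numeric(stats::coef(ga$modelStruct$corStruct,
                                      unconstrained = FALSE)),
               tolerance = 1e-4)
})

test_that("location shifts and scale changes act on fits as they must", {
  d <- fixture_dataset(7, n_per_group = 6)
  f0 <- fit_gls_reml(d, "het_cs")
  t0 <- test_fixed_effects(f0)
  c0 <- time_point_contrast(f0, 5)

  d_shift <- dplyr::mutate(d, response = response + 250)
  fs <- fit_gls_reml(d_shift, "het_cs")
  expect_equal(fs$theta, f0$theta, tolerance = 1e-5)
  expect_equal(test_fixed_effects(fs)$statistic, t0$statistic, tolerance = 1e-5)
  expect_equal(time_point_contrast(fs, 5)$pairwise[[1]]$sem,
               c0$pairwise[[1]]$sem, tolerance = 1e-5)

  d_scale <- dplyr::mutate(d, response = response * 3)
  fc <- fit_gls_reml(d_scale, "het_cs")
  expect_equal(sqrt(fc$theta[1:5]), 3 * sqrt(f0$theta[1:5]), tolerance = 1e-4)
  expect_equal(fc$theta[6], f0$theta[6], tolerance = 1e-5)
  expect_equal(test_fixed_effects(fc)$p_value, t0$p_value, tolerance = 1e-5)
  expect_equal(time_point_contrast(fc, 5)$pairwise[[1]]$sem,
               3 * c0$pairwise[[1]]$sem, tolerance = 1e-4)
})

test_that("covariance parameters are recovered across replicates", {
  # spec'd recovery conditions: het_cs truth, n = 12, rho = 0.6
  n_reps <- 1000
  sc <- fixture_scenario("null", rho = 0.6, n_reps = n_reps)
  rhos <- numeric(n_reps)
  s5 <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    f <- fit_gls_reml(simulate_dataset(fixture_params, sc, r), "het_cs")
    rhos[r] <- f$theta[6]
    s5[r] <- sqrt(f$theta[5])
  }
  expect_lt(abs(mean(rhos) - 0.6), 0.05)
  pooled_sd5 <- sqrt(mean(fixture_params$sd[fixture_params$week == 28]^2))
  expect_lt(abs(mean(s5) - pooled_sd5) / pooled_sd5, 0.05)
})

test_that("degenerate data are rejected", {
  y <- matrix(rep(c(1, 2, 3), each = 4), nrow = 4) # zero residual variance
  d <- long_from_matrix(y, rep(c("A", "B"), each = 2))
  expect_error(fit_gls_reml(d, "hom_cs"), "degenerate")
  expect_error(reml_criterion(d, cov_spec("hom_cs", sigma2 = 1, rho = 0)),
               "degenerate")
  # unbalanced data are refused
  d2 <- fixture_dataset(1, n_per_group = 3)
  expect_error(fit_gls_reml(d2[-1, ], "hom_cs"), "balanced")
})
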