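---
title: "Covariance misspecification in repeated-measures analysis: models, simulation design and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Covariance misspecification in repeated-measures analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rmasim)
```

## The model

`rmasim` studies a balanced three-arm longitudinal design: `n` subjects per
treatment arm, each measured at `T = 5` occasions (weeks 1, 7, 14, 21, 28).
The observation vector of subject `s` in arm `g` is

$$y_s \sim \mathcal{N}(\mu_g, \Sigma), \qquad \mu_g \in \mathbb{R}^T,$$

with subjects independent. The fixed-effect structure is the saturated
cell-means model: one mean per treatment × time cell (15 parameters), which
avoids any reference-level ambiguity and makes every contrast an explicit
linear combination of cell means. The residual covariance $\Sigma$ takes one
of five forms:

| kind | diagonal | off-diagonal `(i, j)` | free parameters |
|---|---|---|---|
| `het_cs` | $\sigma_i^2$ | $\sigma_i\sigma_j\rho$ | $T + 1$ |
| `het_ar1` | $\sigma_i^2$ | $\sigma_i\sigma_j\rho^{|j-i|}$ | $T + 1$ |
| `hom_cs` | $\sigma^2$ | $\sigma^2\rho$ | 2 |
| `hom_ar1` | $\sigma^2$ | $\sigma^2\rho^{|j-i|}$ | 2 |
| `unstructured` | free | free | $T(T+1)/2$ |

The AR(1) lag is the difference of measurement *positions*, not of week
labels: the weeks are unequally spaced, but the correlation model treats
them as an ordered sequence of occasions. This is the convention of the
standard repeated-measures software the simulated analyses emulate.

## Why the restricted likelihood profiles down to the covariance

With complete balanced data and a saturated mean model, the GLS estimate of
each cell mean equals the arithmetic per-cell sample mean for *any*
$\Sigma$ (the design matrix is group-wise orthogonal). Writing $S$ for the
sum over subjects of residual outer products about their own cell means,
$N$ for the number of subjects and $G$ for the number of arms, the REML
criterion reduces to

$$\ell_R(\Sigma) = -\tfrac12\Big[(N-G)\log|\Sigma| + \operatorname{tr}(\Sigma^{-1}S)
  + T\textstyle\sum_g \log n_g + (N-G)\,T\log 2\pi\Big].$$

Each evaluation costs one $T\times T$ Cholesky factorisation, so a fit is a
six-dimensional (or two-dimensional) smooth optimisation over covariance
parameters only. The constant terms are kept so that the value agrees
exactly with `nlme::gls(..., method = "REML")`; the test suite asserts that
agreement (log-likelihood, $\hat\rho$, $\hat\sigma_t$) to optimizer
precision on CS and AR(1) fits. The unstructured optimum is closed-form:
$\hat\Sigma = S/(N-G)$, the pooled within-group sample covariance.

The fixed-effect covariance is block-diagonal,
$\operatorname{Var}(\hat\mu_g) = \Sigma/n_g$, so the standard error for
comparing two arm means at occasion $t$ (the "SEM" throughout) is
$\sqrt{2\hat\Sigma_{tt}/n}$: constant over $t$ under homogeneous fits,
tracking the per-week variance under heterogeneous ones. That structural
fact — not any estimation artefact — is what drives the distorted per-week
error rates under misspecification, and it holds exactly on every fit (a
per-replicate assertion in the tests).

## Generating parameters

`param_table()` compiles the published 3 × 5 table of means, SEMs and SDs
(grams) digitised from a mouse folate-diet growth trial; the same values
ship as `inst/extdata/table1.csv`. Three choices deserve note:

- **SD rule.** The SDs satisfy SD = SEM × √12 (the donor study's group
  size) within digitisation rounding, and the conversion is fixed at
  n = 12 regardless of the simulated group size: the SDs describe the
  population, not the simulated design.
- **Null means.** The per-week null means (160, 480, 630, 724, 800 g) are
  used verbatim as the declared generating parameters even where they are
  not the exact average of the three arm means (week 28 averages 796.7);
  they are the published values and nothing downstream depends on the
  discrepancy.
- **Group-specific generating covariance.** Each arm's $\Sigma_g$ is built
  from that arm's own SD column (common $\rho$), under both hypotheses —
  the extracted per-arm SDs are part of the study conditions. The *fitted*
  structures, in contrast, pool a single $\Sigma$ across arms, as the
  standard RMA formulation does; the "correct" model is therefore correct
  in form rather than in per-arm scale, which mirrors the analysis
  practice under study.

## The simulation grid and its defaults

`scenario_grid()` crosses 2 generating structures × 3 group sizes
(n = 3, 6, 12) × 4 correlations (ρ = 0.1, 0.3, 0.6, 0.9) × 2 hypotheses
(null, alternative) = 48 scenarios, 1000 replicates each by default, with
rejection level α = 0.05 and strict inequality `p < α` (the first histogram
bin is exactly the rejection proportion). All three analysis methods see
the *same* replicate datasets (common random numbers), which sharpens
method contrasts without biasing any marginal rate.

Randomness is counter-seeded: replicate `r` of scenario `s` uses
`base_seed + (slot(s) - 1)·10⁶ + r`, where `slot` is the scenario's
position in the canonical grid. Any replicate can thus be regenerated in
isolation, results are independent of execution order, and all seeds stay
below 2³¹.

### What the generator emulates — and what it does not

The generator reproduces multivariate-normal, complete, balanced growth
data with increasing per-week variance and exchangeable or AR(1)
within-subject correlation. It does **not** emulate dropout or missing
weighings, non-normal (e.g. skewed or heavy-tailed) weight distributions,
truncation at biologically implausible values (a negative week-1 draw has
probability ~10⁻⁸ and is kept as-is), or covariates such as litter or
cage. Passing tests therefore demonstrate calibration and power properties
under the idealised conditions; they do not certify behaviour under
missingness or non-normality.

## Numerical choices

- **Optimizer.** BFGS on an unconstrained scale: log variances, and a
  scaled logit mapping $\rho$ onto $(-1/(T-1), 1)$ for CS (the positive
  definiteness bound at $T$ occasions) or $(-1, 1)$ for AR(1). The
  simulation grid only uses $\rho \in [0, 1)$, but the fitting range is
  left wider so sampling noise near $\rho = 0$ cannot push the optimum
  against an artificial boundary.
- **Starting values.** Per-occasion pooled variances (diagonal of
  $S/(N-G)$) and the mean lag-1 correlation of the pooled residual
  correlation matrix; up to three deterministically jittered restarts on
  failure.
- **Convergence.** Relative criterion change below 1e-12 within `optim`
  plus a numerical gradient norm below 1e-5 × max(1, |criterion|) at the
  reported optimum. Non-converged replicates are excluded from that
  method's denominators; `run_scenario()` warns if exclusions exceed 1% in
  any cell (across the workhorse scenarios they are in practice zero).
- **Degenerate inputs.** Zero within-group residual variation, unbalanced
  or incomplete subjects, fewer than two arms or two subjects per arm, and
  non-positive-definite trial covariances are rejected with descriptive
  errors. Positive definiteness uses a scale-relative eigenvalue tolerance
  (1e-10 × the largest diagonal entry).
- **Denominator df.** The Wald F statistics use Satterthwaite denominator
  df by default: the observed information of the covariance parameters is
  replaced by the analytic *expected* REML information
  $\mathcal{I}_{kl} = \tfrac{N-G}{2}\operatorname{tr}(\Sigma^{-1}\partial_k\Sigma\,
  \Sigma^{-1}\partial_l\Sigma)$ (exact, cheap, and far better conditioned
  than finite differences across parameters spanning four orders of
  magnitude), and multi-df contrasts are combined by the usual
  eigenvector decomposition. `"residual"` ($NT-GT$) and
  `"between-within"` ($N-G$ for between-subject contrasts,
  $(N-G)(T-1)$ for within) are available for sensitivity; at n = 12 all
  three give denominator df ≥ 33 for the per-week contrasts and
  near-identical rejection rates. If the information matrix is singular
  the df fall back to between-within.
- **Per-week "treatment effect".** Implemented as the joint 2-df equality
  contrast of the three arm means at that week — a single p-value per week
  panel — with all three pairwise t contrasts and their SEMs additionally
  exposed via `time_point_contrast()`.

## Problem sizes in the shipped checks

The package's own end-to-end checks run the two scenarios examined in
detail (het CS truth, ρ = 0.3, n = 12; null and alternative) at the full
1000 replicates, plus a 200-replicate scaled rerun with correspondingly
widened (±3 binomial SE) Monte-Carlo bands; moment-recovery properties use
800–2000 replicates of the generator alone. These sizes make the Monte-Carlo
error small relative to every asserted band while keeping a complete run of
the suite in the minutes range on a single core. The full 48-scenario grid
at 1000 replicates is a `run_config()` call away and runs unattended.

## Known limitations

- Only non-negative ρ and the five listed structures are supported; no
  Toeplitz, ante-dependence or factor-analytic structures, and no
  random-effects (G-side) formulation.
- No missing-data likelihood: the fitter requires complete balanced data,
  by design (the phenomenon under study is defined on complete data).
- Kenward–Roger df are not implemented; Satterthwaite is the default and
  the two are practically indistinguishable at the grid's group sizes.
- No multiplicity adjustment across the five per-week tests: the object of
  study is the raw per-week error rate.
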