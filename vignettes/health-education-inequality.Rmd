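---
title: "Measuring consumption-related inequality in health education"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring consumption-related inequality in health education}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(healthineq)
```

## The problem

Health education — knowing how infections spread, what prevention works,
where to find reliable information — behaves like any other good: households
with higher living standards accumulate more of it. `healthineq` quantifies
that gradient for a survey-based health-education score, ranked by a
household-consumption composite, using the standard toolkit of
health-economics inequality measurement: the concentration index, its
Wagstaff decomposition into per-factor contributions, and the horizontal
inequity index after need standardization. A seeded synthetic-survey
generator with a fully known data-generating process backs every estimator
with ground truth.

## Score construction

The outcome sums four health-education items, each scored 0–8 with 0 for
"do not know", onto 0–32. Because zero totals occur, the log transform is
`ln(1 + total)`; the raw total is always retained and either scale can be
selected as the analysis outcome (`outcome = "log_total"` or `"total"` in
`pipeline_config()`). The default is the log scale, which is also the scale
on which the simulator's linear model operates, so that simulated-data
regressions estimate the model that actually generated the data.

The exposure compresses five Likert consumption dimensions into one index:
items are reverse-coded so higher = more consumption, z-scored, weighted by
the first eigenvector of their correlation matrix (correlation, not
covariance: the dimensions are not on a common scale), and min–max
standardized to [0, 1]. The sign convention — largest-magnitude loading
positive — removes the eigenvector sign ambiguity, making the composite
invariant to column order and to positive affine rescaling of any input.
Cronbach's α and the explained-variance ratio are reported alongside;
α refers to the five consumption dimensions. No rotation, polychoric
correlations, or multi-component indices are attempted.

Income enters as quantile groups. Group labels are assigned from cut-points
computed on the *distinct* values, with observations equal to a cut-point
going to the lower group; this tie-to-lower rule keeps heavily tied
distributions from splitting a tied block across groups.

## Concentration index and conventions

With sampling weights `w`, weighted midpoint fractional ranks `R` in the
ranking-variable distribution (tied blocks share the block midpoint; the
weighted mean of `R` is exactly 1/2) and mean outcome `μ`,

$$CI = \frac{2}{\mu}\,\mathrm{Cov}_w(y, R).$$

All covariances here are population-weighted (denominator `Σw`), which is
what makes the decomposition identity exact. Three routes to the same number
are implemented and cross-checked in the tests: the covariance formula, the
convenient-regression slope (`2σ²_R (y_i/μ)` on `R_i`, robust HC1 standard
error on the slope), and twice the signed area between the concentration
curve and the diagonal. Curve points aggregate tied ranking values into a
single step so the curve is invariant to within-tie ordering, and with
midpoint ranks the trapezoidal area route agrees with the covariance route
to numerical precision rather than only asymptotically.

Sign convention: the curve below the diagonal, and CI > 0, mean the outcome
is concentrated among the better-off (pro-rich). This is the standard usage
in the health-economics literature; verbal descriptions that invert it
(curve below the line = concentration among the poor) are not honored. The
index is scale-invariant (`ci(c·y) = ci(y)` for `c > 0`) but not
translation-invariant (`ci(y + c) = ci(y)·μ/(μ + c)`), and both properties
are asserted in the tests. No Erreygers/Wagstaff bounded-outcome correction
is applied by default — the plain CI on the 0–32 score is the primary
quantity — but both are available through the `correction` argument of
`concentration_index()` with explicit scale bounds. The index requires a
strictly positive mean outcome.

## Decomposition and horizontal inequity

For the linear model `y = α + Σ_k β_k x_k + ε` (weighted OLS on the analysis
covariate set),

$$CI = \sum_k \underbrace{\frac{\beta_k \bar x_k}{\mu}}_{\eta_k} C_k +
\frac{GC_\varepsilon}{\mu},$$

where `C_k` is the concentration index of factor `k` against the *same*
ranks and the residual term is the generalized concentration index of the
regression residuals over `μ`. Contributions are computed directly as
`2 β_k Cov_w(x_k, R)/μ`, which stays defined when a factor mean is zero
(the per-factor `C_k` is then reported as `NA`). The adding-up identity is
exact by linearity of the covariance and is asserted to `1e-10` on every
pipeline run rather than assumed.

Horizontal inequity subtracts only the need-factor contributions:
`HI = CI − Σ_{k∈need} η_k C_k`. The default need set is gender, education
years, health status, and age (entering the model as age squared). A
definition that subtracted need, non-need, and residual terms alike would
make HI identically zero, so it is not implemented. The decomposition
covariate set defaults to the exposure plus the Lasso-selected controls;
the residual is always computed and reported.

Subgroup analysis re-ranks within each stratum (income tertiles by default)
and reports per-stratum CI, HI, and the mean ± SD of the outcome by quartile
of the ranking variable; strata under a configurable floor (default 30 rows)
are skipped with a warning. Uncertainty for HI and contribution shares is
available from a seeded nonparametric bootstrap (default 1,000 draws);
significance stars in the regression table reflect per-row tests with no
multiplicity adjustment, and that is deliberate — the reporting mirrors
common practice for these tables.

## Covariate selection

The Lasso minimizes `(1/2n)·RSS + λ·Σ pf_j |β_j|` by cyclic coordinate
descent with soft-thresholding (compiled core in `src/lasso_cd.cpp`),
on internally standardized columns with an unpenalized intercept;
convergence is a maximum standardized-coefficient change below `1e-8`, with
a hard cap of `1e5` sweeps and an explicit error (never a silent partial
result) on non-convergence. The `1/2n` scaling makes λ comparable across
sample sizes; published λ values under other scalings are not comparable to
ours. The path runs over a 50-point log-spaced grid from `λ_max` (the
smallest penalty with an all-zero solution) down to `λ_max·10⁻⁴`, with warm
starts. Cross-validation uses a seeded 10-fold random partition; the default
"min" rule breaks exact ties toward the larger (sparser) λ, and a "1se" rule
is available. Per-column penalty loadings are uniform, except that optional
city/community fixed-effect blocks get zero loadings: treated as controls,
never as selected covariates. The pipeline default leaves fixed effects out
(`fixed_effects = "none"`) because the simulator gives cities and
communities no true effect, so several hundred dummies would only dilute
ground-truth recovery; flag them on for data where place effects matter.

The exposure coefficient comes from post-double-selection: Lasso of outcome
on controls, Lasso of exposure on controls, then OLS of the outcome on the
exposure and the union of the two active sets, with HC1 robust standard
errors. With no controls this reduces exactly to the simple OLS slope.
Inference for the selected controls themselves is out of scope.

## The synthetic-survey generator

The generator's job is to emulate the marginal structure of a large
cross-sectional consumption/health-education survey while keeping the
data-generating process fully known.

*Rank structure.* A Gaussian copula links every covariate to a latent
consumption factor. Because the concentration index depends on the data only
through ranks, the copula separates exactly what matters (rank dependence)
from what does not (marginal shapes). Discretizing a margin attenuates rank
correlations, so the latent correlation for each covariate is calibrated
numerically (quadrature plus root-finding on the population Spearman of the
discretized margin) to hit the *post-discretization* target; targets beyond
what a margin can support raise a configuration error naming the covariate.
Achieved Spearman correlations at n ≥ 5,000 land within 0.05 of target.

*Marginals.* Defaults reproduce the published sample: gender share 0.51,
mean education 9.86 years on six attainment levels, 59% married, 44% rural,
37% privately insured, five-level self-reported health, income quantile
groups, ages 18–80 (truncated normal, mean 35), 85 cities and 301
communities. Weights default to 1 (self-weighting); a stratified option
assigns community weights inversely proportional to sampling probability.
The original stratum-weighting rule (minimum 30 participants per stratum)
is not reproduced.

*Outcome model.* The latent outcome is linear on the log scale:
`ℓ = α + Σ β_k x_k + ε`, `ε ~ N(0, σ_ε)`, and the stored score is
`round(exp(ℓ) − 1)` censored to 0–32, split into four exchangeable 0–8
items by a multivariate hypergeometric draw (a deterministic balanced split
is available via `item_noise_sd = 0`). Defaults: exposure effect 0.30 per
unit of the composite; α and σ_ε set by lognormal moment-matching so the
*latent* score has mean 12.17 and SD 7.72 (σ_ε = 0.517); covariate effects
sized so the population CI of the outcome against consumption rank is about
0.032, with consumption and annual income the leading contributors. The
five consumption items load 0.77 on the latent factor, which yields a
realized (post-discretization) Cronbach's α near 0.85.

*What the generator does not emulate.* Snowball/recruitment artifacts,
non-response, within-household clustering beyond the community label,
measurement error correlated with covariates, and real-world deviations
from the single-factor consumption structure. Passing tests on generated
data therefore demonstrate estimator correctness under a known model, not
robustness to every feature of field data.

*Ceiling censoring and the recovery estimand.* Matching the published score
mean and spread on a 0–32 scale necessarily puts mass (~3%) at the ceiling.
OLS on the censored score then targets a slightly attenuated coefficient
(about 2% below the latent-model value for the default configuration: the
flat region above the cap contributes zero slope). The generator therefore
stores `latent_outcome`, the exact linear-model outcome before rounding and
censoring: parameter-recovery checks use it (the estimand there is exactly
the configured β), while inequality measures use the realistic bounded
score. `expected_ci()` likewise has no closed form once the score is
censored, so it is a documented Monte-Carlo approximation from one large
draw (default 10⁶ rows), with the closed-form linear decomposition
`Σ η_k C_k` attached as an attribute.

## Numerical choices and degenerate inputs

- Weighted covariances use the population denominator `Σw`; integer weights
  are exactly equivalent to row replication.
- Fractional ranks are strictly inside (0, 1); all-tied ranking variables
  give every row rank 1/2 and a zero CI, but make the convenient-regression
  standard error undefined.
- Constant columns: a constant consumption dimension, control, or factor
  raises a named error rather than propagating NaNs; within-stratum
  subgroup models silently drop factors that are constant *in that stratum*
  only.
- Min–max standardization requires at least two distinct values.
- CV folds are a seeded random partition; identical seeds give identical
  fold assignments, paths, selected λ, and byte-identical pipeline JSON.
- All pipeline randomness derives from one root seed split into fixed
  per-stage substreams, so stages can be re-run in isolation.

## Problem sizes used in the tests

The test suite exercises: 200 random micro-tables (n ≤ 50) for the
three-route CI equivalence; orthonormal designs (n = 256, p = 8, 50-point
λ grid) against the soft-threshold closed form; a glmnet cross-check of the
coordinate-descent core; 50 full-size replicate surveys (n = 7,715) for
exposure-effect recovery and CI calibration; 100 replicates (n = 1,500) for
the need-only horizontal-inequity construction; and byte-identity of
repeated pipeline runs. These sizes were chosen to give each check clear
statistical resolution while keeping the suite comfortably runnable on a
single CPU.

## Limitations

- Cross-sectional, observational: nothing here identifies causal effects of
  consumption on health education.
- The plain CI on a bounded score does not satisfy the mirror property;
  the bounded-outcome corrections are deliberately not the default.
- Post-selection inference covers the exposure coefficient only.
- The convenient-regression standard error ignores the estimation of ranks
  and μ; for small samples prefer the bootstrap.
- λ values are objective-scaling-specific and not transferable across
  software with different scalings.
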