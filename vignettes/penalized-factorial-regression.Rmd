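---
title: "Penalized factorial regression for G×E prediction: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Penalized factorial regression for G×E prediction: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gxenet)
```

## The model

`gxenet` predicts the performance of *tested* genotypes in *untested*
environments from environmental covariates (ECs). Each genotype carries a
linear reaction norm:

$$Y_{ij} = \mu + g_i + e_j + \sum_{t=1}^{n_c} v^{(t)}_{ij}\,\beta_{it} +
\varepsilon_{ij},\qquad \varepsilon_{ij}\sim N(0,\sigma^2)\ \text{i.i.d.}$$

`g_i` and `e_j` are genotype and environment main effects; `beta_it` is
genotype *i*'s sensitivity to EC *t*; `v` may be environment-level (one value
per trial) or genotype-specific (one value per genotype-by-environment cell,
as for covariates windowed on each genotype's phenology). Identifiability is
by treatment coding: the first genotype and the first environment (in
first-appearance order of the input file) have `g = e = 0`. Treatment coding
keeps the design columns sparse and lets the fitted `g_i` transfer directly
into predictions; a sum-to-zero parameterisation would densify the dummy
columns without changing any prediction.

The design has `p = n_g + n_e - 1 + n_g n_c` columns — `n_c + 1` free
parameters per genotype — so `p` routinely rivals or exceeds the number of
observations and the sensitivities must be regularised. The fitted objective
is

$$\frac{1}{2N}\,\mathrm{RSS}(\theta) + \lambda \sum_k w_k\left(
\alpha|\theta_k| + \tfrac{1-\alpha}{2}\theta_k^2\right),$$

with penalty factors `w_k = 0` on the intercept and all main effects and
`w_k = 1` (or a positive per-genotype weight) on sensitivity columns.
Main effects are left unpenalized deliberately: environmental main effects
are typically an order of magnitude larger than the G×E signal, and a shared
penalty would trade severe shrinkage of `e_j` against almost none on the
sensitivities. The `1/(2N)` scaling makes one `lambda` comparable across
datasets of different size. `alpha` is 0 for ridge, 1 for lasso and 0.5 for
the default elastic net.

### Prediction and evaluation

For a new environment only the ECs are known, so the prediction is
environment-centred:
$$\hat y_{ij} = \hat\mu + \hat g_i + \sum_t \tilde v^{(t)}_{ij}\hat\beta_{it},$$
with no `e_j` term. Because accuracy is measured *within* environments — the
Pearson correlation between predicted and observed values per environment,
averaged over environments (APCOR\_Env) — the missing per-environment
constant is irrelevant. APCOR\_Env here is the **unweighted** mean over
environments with a defined correlation; a cell-count-weighted variant is
available (`apcor_env(..., weighted = TRUE)`). Environments with fewer than
3 observed cells or zero variance in either vector are excluded from the
mean and reported, since the correlation is undefined or degenerate there.
The evaluation target is configurable: observed phenotypes, or true genetic
values when the data come from the simulator (the natural target when the
noise-free truth exists).

## EC standardization

Each EC is centred and scaled to mean 0, sd 1 using **training cells only**
(training environments; for genotype-specific ECs, cells of genotypes present
in the phenotype table); test ECs are transformed with the stored training
statistics. This makes a single `lambda` act comparably on ECs measured in
different units — without it the penalty would be dominated by whichever
covariate happens to have small numerical range. The switch
`standardize = FALSE` is exposed for pre-scaled inputs. Standardization is a
choice of parameterisation: fitted values and predictions are invariant to
rescaling any EC (tested), and the sensitivity matrix is reported on both
scales (`B` original, `B_std` standardized).

An EC that is constant on the training set has no information and an
undefined standardization; the design builder refuses it by name rather than
silently producing an all-zero column.

## Rank structure of the unpenalized model

With environment-level ECs the `lambda = 0` ("Full") factorial regression is
*exactly* rank-deficient: for each EC, the sum of its `n_g` sensitivity
columns equals that EC's value repeated within each environment — an
environment-indexed vector already spanned by the intercept and environment
dummies. The Full model is therefore only estimable with genotype-specific
ECs (which break the collinearity), and `fit_full()` raises a rank error
otherwise, pointing at penalization. The penalized fits are unaffected. This
also explains why trial networks with genuinely environment-level covariates
*need* the penalty even when `N > p`.

## The solver

Three exact-to-tolerance routes, chosen by the penalty:

* **`lambda = 0`** — sparse QR least squares (`Matrix::qr`), with rank
  deficiency detected from the R factor's diagonal and reported as an error
  advising a positive penalty.
* **Ridge (`alpha = 0`)** — the unpenalized columns are profiled out through
  their QR factorisation; the penalized block (scaled by `1/sqrt(w_k)` to
  reduce weighted to unit ridge) is projected onto their orthocomplement and
  its Gram matrix eigendecomposed once. Every `lambda` on the path then
  costs one diagonal backsolve, so a 100-point path is barely more expensive
  than a single fit, and values as small as `1e-8` (used for noise-free
  recovery checks) are handled without iteration.
* **`alpha > 0`** — coordinate descent in compiled code on the sparse design
  (residual updates, one pass costs `O(nnz(X))`), warm-started along the
  decreasing grid from the main-effects-only least-squares fit. That start
  makes the `lambda >= lambda_max` endpoint *exact*: the additive solution
  with all sensitivities identically zero, matching the theoretical limit.

`lambda_max` is computed after profiling out the main effects:
`max_k |x_k' r_0| / (N alpha w_k)` over sensitivity columns, where `r_0` is
the main-effects residual; it is inflated by `1e-8` relatively so the
all-zero endpoint survives floating-point roundoff. The automatic grid is
100 log-spaced values down to `lambda_max * 1e-4`. Ridge has no finite
all-zero point, so its grid is anchored at the lasso-equivalent
`lambda_max * 1e3`.

Convergence is declared when the largest per-coordinate update, scaled to
fitted-value units (`|delta| * sqrt(x_k'x_k / N)`), drops below
`tol * sd(y)`, with `tol = 1e-4` by default. The KKT residual at exit is
about `3 * tol` in the same units. The default is deliberately of the
tightness class used by production coordinate-descent solvers: on correlated
reaction-norm designs CD converges linearly, and pushing the tolerance from
`1e-4` to `1e-6` multiplies runtime roughly thirtyfold while moving
cross-validated `lambda` selection and every accuracy statistic by far less
than their Monte-Carlo noise. Where a certified stationary point matters
(the KKT property tests), `tol` is an argument; `kkt_violation()` computes
the exact residual of any candidate solution.

## Cross-validation

Two fold schemes (`make_folds()`), both pure functions of an explicit seed:

* **random** — G×E observations partitioned near-uniformly, environments
  ignored; 10 folds by default.
* **stratified** — *environments* partitioned into folds, every observation
  following its environment. A held-out environment's dummy column is then
  all-zero in the fold's training block, so its main effect is fixed at 0 —
  exactly the information available for a genuinely new environment. The CV
  criterion is the mean over folds of the held-out mean squared error; under
  stratified folds that error contains the irreducible `e_j` offsets, which
  shifts the curve but hardly moves its argmin, and is consistent with the
  environment-centred prediction task.

The selected value is `lambda_cv.min` (error-minimising; ties go to the
larger `lambda` because the grid is scanned from above); the one-standard-
error rule is exposed as `select = "1se"`. If the CV curve is flat to
`1e-12` across the grid — every `lambda` beyond `lambda_max`, for instance —
the largest value is returned with a warning.

### Genotype-specific penalties

Optionally the sensitivity penalty can differ per genotype
(`genotype_weights`, default all 1). `tune_genotype_weights()` runs a second
CV loop over a small multiplier grid. Because each genotype's sensitivity
columns occupy disjoint rows (coupling with other genotypes only through the
shared main effects), the cross-validated error of genotype *i* under a
multiplier is read off from a fit in which *all* genotypes share that
multiplier — costing one CV per multiplier instead of one per genotype ×
multiplier. Each genotype then receives its own argmin and the model is
refit once. This is off by default: with few training observations per
genotype the extra tuning noise tends to cost more accuracy than the
flexibility gains.

## Baselines and the marker stage

`fit_additive()` fits the main-effects-only model — the exact large-`lambda`
limit of every penalized fit (verified to machine precision in the tests)
and the reference any reaction-norm model must beat. `fit_full()` is the
unpenalized factorial regression; on data with many candidate ECs it
overfits in the characteristic way: highest training accuracy, lowest test
accuracy among the factorial fits.

`stage2_marker_ridge()` extends predictions to genotypes never phenotyped:
the fitted `g_i` and each column of the (standardized-scale) sensitivity
matrix are regressed on centred marker dosages by independent univariate
ridge, with per-response shrinkage chosen by generalized cross-validation on
one shared SVD. Univariate ridge is chosen over a multivariate BLUP for
speed and simplicity; a multivariate stage is a natural extension. Missing
dosages are imputed to the marker mean (deterministic). `predict_gnen()`
then pushes marker-predicted parameters through the same environment-centred
arithmetic; it requires environment-level ECs, since genotype-specific
covariates depend on phenology that is unobservable for untested genotypes.
Held-out-genotype accuracy of this stage is capped near
`sqrt(n_train / (n_train + n_markers))` for independent markers — the test
suite exercises it at sizes (300 genotypes, 100 markers, 20 causal) where
the signal is genuinely recoverable.

## The simulator

`simulate_met()` generates the offline test bed the package is validated on.
What it emulates:

* **Envirotypes** — trials belong to discrete environmental scenarios
  (default five, equal frequency, as in drought-stress characterizations of
  maize trial networks); a trial's ECs are Gaussian around its scenario's
  mean vector (scenario means drawn once per seed with unit spread,
  within-scenario sd 0.5). Training and test environments are drawn from the
  same scenario frequencies, so test conditions are represented in training —
  the regime in which covariate-based transfer can work at all.
* **Genotype-specific ECs** (default) — Gaussian phenology jitter of sd 0.25
  around the environment value, emulating development-dependent covariate
  windows; `mode = "env_level"` switches it off.
* **Sparse reaction norms** — `n_active` of the `n_c` ECs carry signal;
  active sensitivities are drawn independently across genotypes
  (sd `sensitivity_scale`), inactive ones are exactly zero. An optional
  marker mode makes `g` and the active slope columns marker-determined
  (`B = M Gamma` with `n_causal` causal markers) for stage-2 tests.
* **Heritability-calibrated noise** — per-environment error variance
  `sigma2_j = Var_i(genetic value) * (1 - h2)/h2`, so the expected
  within-environment heritability equals the target (default 0.5, the
  mid-heritability regime trial networks are usually powered for).

Default sizes (50 genotypes, 60 training + 20 test environments, 20 ECs with
3 active, `sd_e = 2 > sd_g = 1 ≈` G×E scale, trait mean 6) describe a
mid-sized trial network in which environment effects dominate, genotype main
effects and G×E are comparable, and the accuracy ceiling set by `h2 = 0.5`
is around 0.7 — the regime where penalization visibly matters.

What it does **not** capture, and hence what passing tests cannot show about
real data: plot-level replication and spatial field trends (the model works
on genotype-by-environment means), correlation structure among ECs within a
scenario (default independent; a correlation matrix can be supplied through
custom envirotypes), linkage disequilibrium among markers, non-Gaussian
errors, and reaction-norm nonlinearity. Real covariates are also measured
with error and chosen by agronomic insight; the simulator's ECs are exactly
the generating variables, which flatters all methods equally.

## Numerical choices and degenerate inputs

* Ties in CV error resolve to the larger `lambda`; ties in GCV to the first
  (largest) grid point scanned.
* `sigma2_hat` is RSS over `N - df` with `df` the nonzero-coefficient count,
  falling back to `N` when saturated.
* Duplicate genotype-environment cells, non-numeric trait values, missing EC
  coverage for any requested cell, constant training ECs (with
  standardization on), single-genotype or single-environment designs, and
  stratified `k > n_e` all raise typed errors early rather than propagating
  `NA`s.
* Fold assignment, the simulator and the fitting pipeline take explicit
  seeds and restore the caller's RNG state (`withr::with_seed`); equal seeds
  reproduce byte-identical results.
* Unit and acceptance tests run at deliberately modest sizes (tens of
  genotypes and environments; the multi-seed overfitting experiment uses
  50 × 80 cells over ten seeds; the heritability check 500 genotypes), which
  keeps the full suite in a few minutes while leaving every property
  measurably far from its threshold.

## Known limitations

Only linear reaction norms are modelled — quadratic, interaction or spline
terms in the ECs multiply the parameter count per genotype and, in this
family of models, tend to overfit quickly without additional structure
(grouped selection across genotypes would be the natural next step).
Prediction outside the envirotypes spanned by training remains
extrapolation, penalized or not. The residual G×E not captured by the ECs is
absorbed into the error term and cannot be separated from measurement noise
at the means level. The stage-2 extension inherits the accuracy limits of
univariate genomic prediction for parameters that are themselves estimates.
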