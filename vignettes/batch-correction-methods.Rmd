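---
title: "Location/scale batch correction and model selection: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Location/scale batch correction and model selection: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metabatch)
```

## The measurement model

`metabatch` treats a multi-batch LC–MS feature table as draws from a
location/scale (L/S) batch model on the log2 scale. For feature $g$,
sample $j$ acquired in batch $i$,

$$ y_{ijg} = \alpha_g + X_j\beta_g + \gamma_{ig} +
\delta_{ig}\,\varepsilon_{ijg}, \qquad \varepsilon \sim N(0,\sigma_g^2), $$

where $\alpha_g$ is the feature's baseline, $X_j\beta_g$ any biological
signal to be preserved, $\gamma_{ig}$ an additive batch offset and
$\delta_{ig}$ a multiplicative batch scale. All corrections in the package
estimate and invert the $(\gamma, \delta)$ imprint; they differ in how the
estimates are stabilized.

Assumptions shared by the statistical models: intensities are
approximately Gaussian per (feature, batch) after the log2 transform;
batch effects are exchangeable across samples within a batch (no
residual within-batch structure beyond the optional drift term); and the
biological design is not confounded with batch — a batch perfectly
aligned with a covariate is a hard error, not a warning.

### Identifiability

Batch offsets are only defined relative to a reference. Every fit in the
package uses the sample-size-weighted sum-to-zero constraint
$\sum_i n_i \gamma_{ig} = 0$, which makes $\alpha_g$ the grand mean of the
fitted samples and avoids privileging a reference batch. A consequence
worth knowing when validating against simulations: if true offsets are
drawn i.i.d. per (feature, batch), only their per-feature weighted-centered
version is estimable; `centered_gamma_true()` applies the same centering
to the simulator's truth for recovery comparisons.

## The two-stage regression model (ber)

Stage 1 fits $y = \alpha_g + X\beta_g + \gamma_{ig}$ by least squares
under the constraint above and subtracts the fitted batch offsets. Stage 2
estimates a per-batch residual scale $\hat s_{ig}$ from the stage-1
residuals, divides each residual by its batch scale and multiplies by the
pooled scale $\hat s_g$, then re-adds $\hat\alpha_g + X\hat\beta_g$.

We estimate $\hat s^2_{ig}$ as the *unbiased* within-batch variance of the
residuals (denominator $n_i - 1$) rather than the per-batch mean squared
residual a plain regression of squared residuals on batch indicators would
give. The two coincide for balanced designs; with unequal batch sizes only
the unbiased version makes the corrected per-batch variances exactly equal
— which is the property users rely on and the test suite asserts.

With no covariates, corrected per-batch means are equal to numerical
precision and per-batch variances are equal by construction; the procedure
is exactly idempotent.

**Bagged ber.** The stage-1/stage-2 parameters are re-estimated on
stratified bootstrap replicates (resampling with replacement *within* each
batch, so batch sizes are preserved) and averaged; the correction is then
applied once to the original data with the averaged parameters. This is a
partial bagging — parameters are bagged, predictions are not — which keeps
the corrected table a deterministic function of one parameter set and
makes the fit reproducible from its `internals`. The default of 150
replicates follows the convention for this correction family; a replicate
in which some batch collapses onto a single resampled sample has an
undefined scale and is redrawn (at most 100 consecutive redraws, then an
error — reachable only for batches of 2–3 samples). The bootstrap uses a
caller-supplied seed and restores the global RNG state.

## Empirical-Bayes ComBat

Step 1 standardizes: the full model (including batch) is fitted per
feature; $\hat\sigma^2_g$ is the pooled residual variance (denominator
$N$, matching the reference implementation); $Z = (Y - \hat\alpha_g -
X\hat\beta_g)/\hat\sigma_g$ retains the batch structure. Step 2 computes
per-batch moments $\hat\gamma_{ig}$ (mean) and $\hat\delta^2_{ig}$
(unbiased variance) of $Z$ and shrinks them across features:

* **Parametric:** $\gamma_{ig} \sim N(\bar\gamma_i, \bar\tau_i^2)$ and
  $\delta^2_{ig} \sim$ Inverse-Gamma$(\bar\lambda_i, \bar\theta_i)$, all
  hyperparameters by method of moments across features; the posterior
  estimates are the fixed point of the coupled updates (see
  `?combat_correct`), iterated per batch until the maximum absolute
  relative change falls below `tol` (default `1e-4`, the customary value
  for this iteration; cap `max_iter = 500`, exceeding it is an error that
  reports the trailing change trace). The iteration starts at the observed
  moments. Note the moment estimator gives $\bar\lambda_i = 2 +
  \bar V_i^2/S_i^2 > 2$ whenever $S_i^2 > 0$; the guard for
  $\bar\lambda_i \le 1$ (an undefined prior mean) is therefore defensive,
  and the practically reachable degenerate case is $S_i^2 = 0$ (e.g.
  duplicated features), which errors with a pointer to the nonparametric
  mode.
* **Nonparametric:** the posterior mean for feature $g$ in batch $i$
  weights every *other* feature's $(\hat\gamma_{ig'}, \hat\delta^2_{ig'})$
  by the Gaussian likelihood of batch-$i$ data of feature $g$ under those
  parameters. The feature itself is excluded (leave-one-out) so it cannot
  anchor its own posterior; weights are computed with log-sum-exp and
  renormalized to 1.

Step 3 rescales, re-centers and re-adds the preserved systematic part.
Covariates always enter estimation and are always re-added — biology is
adjusted *around*, never removed. There is no reference-batch or mean-only
variant: all batches shrink toward the pooled parameters.

ComBat is idempotent only in the large-sample limit: a second pass
re-estimates scale factors from finite data and re-shrinks them, changing
entries at the order of the moment-estimation noise
($\propto \sqrt{2/n_i}$, halved by shrinkage), not at machine precision.
The suite therefore checks ber idempotence at `1e-6`·SD and ComBat
idempotence at the same 5%-of-SD tolerance as the null-case consistency
check (600 samples, 40 features), which that sampling argument predicts.

## The QC-lowess comparator

Per feature and (by default) per batch, `stats::lowess` — tricube weights,
`iter = 2` robustness iterations, span `frac = 0.5` — smooths the QC
intensities against injection order; the curve is evaluated at every
sample's order by linear interpolation and held constant beyond the first
and last QC (linear extrapolation can blow up at run edges). Correction is
the ratio to the feature's median QC level on the raw scale, or the
equivalent subtraction on the log2 scale. The span and robustness settings
are the package's own defaults for sparse QC series (a handful of QCs per
batch); they are deliberately mild so an exactly linear drift is
reproduced exactly.

Features with fewer than 3 usable QC measurements in any fitting window,
or a non-positive fitted level on the raw scale, are dropped and reported
with a reason code — the structural blind spot of QC-based correction that
the statistical models do not share: a compound diluted below the
detection limit in the pooled QCs is unrecoverable by this route no matter
how well the study samples measure it. Whether drift should be fitted per
batch or across the whole run is genuinely data-dependent; per batch is
the default because between-batch jumps are usually discontinuous, and
`per_batch = FALSE` covers long continuous runs.

## The selection score

For each feature, the adjusted $R^2$ of intensity on batch membership
(one-way fit, QCs excluded, pairwise-complete observations) measures
surviving batch dependence; a dataset's score is the maximum over
features, clipped below at 0. Two conventions coexist in practice —
"maximum absolute" versus "0 to 1" — and they disagree precisely when all
per-feature values are negative, which is the signature of a successful
correction (the adjustment penalty $\,(n-1)/(n-B)\,$ pushes a no-signal
fit below zero). The package reports both: `score` (clipped, in $[0,1]$,
used for ranking) and `raw_max` (unclipped, diagnostic). Ranking ties on
the clipped score are broken by the mean adj-$R^2$ — a model that is
consistently low across the whole feature panel beats one with an equal
worst case — and then alphabetically, so rankings are total and
reproducible.

## The simulator: what it does and does not emulate

`simulate_batches()` draws directly from the L/S model above, plus a
linear (optionally sinusoidal) within-batch drift over injection order and
left-censoring at a per-feature detection limit. Defaults
($\gamma_{ig} \sim N(0, 2^2)$, $\delta_{ig} \sim \mathrm{LogNormal}(0,
0.2)$, $\sigma = 0.5$, baselines $N(18, 2^2)$, all log2 units) represent a
strongly batch-dominated acquisition — between-batch variance 4 versus
within-batch variance ≈ 0.28 — the regime in which model comparison is
informative. QC injections bracket each batch (one at the start, one after
every `qc_every` study samples) and carry the batch offset, drift and
scaled noise of their batch around the pooled mean: QCs share the
analytical sources of variation, which is the premise that makes QC-based
correction meaningful at all.

Two presets scale the package's motivating study designs down to
seconds of compute: `targeted_cohort` (11 batches × 20 samples, 100
features, QCs every 10, no censoring — the configuration the acceptance
script uses) and `untargeted_tissue` (3 batches × 25 samples, 500
features, QCs every 8, a two-group design, drift, and LOD censoring).

What the generator does *not* emulate — and hence what passing tests do
not establish about real data: non-Gaussian and heavy-tailed intensity
distributions, correlated features (co-eluting adducts, pathway
co-regulation), nonlinear or discontinuous drift within a batch,
missingness that is not purely left-censored, and retention-time or m/z
artefacts upstream of the feature table. Parameter recovery on simulated
data validates the estimators under their own model, not the model itself.

## Numerical choices and degenerate inputs

* Constrained fits go through one QR decomposition shared by all features;
  rank deficiency is an error naming the collinear columns.
* A (feature, batch) cell with zero within-batch residual variance skips
  the scale step (ratio 1) with a logged message; a feature with zero
  pooled variance is corrected for location only.
* Zero-variance features score adj-$R^2 = 0$ with a warning rather than
  NaN.
* PCA fixes component signs by forcing the largest-magnitude loading
  positive; constant features are excluded from unit-variance scaling
  rather than dividing by zero.
* KDE summaries skip batches with fewer than 2 observations (warning);
  box statistics degenerate to the point.
* `write_feature_table()` prints doubles with `%.17g`, so a write/read
  round trip is bit-exact for finite values; missing entries are empty
  cells (`""`, `"NA"`, `"NaN"` are read back as missing; `0` only when
  the layout opts in, since untargeted exports often use 0 for
  not-detected).
* Missing-value imputation defaults to half the feature's observed
  minimum — the left-censoring convention for MS data, where absence
  usually means "below LOD", not "missing at random"; kNN-by-feature
  correlation is available when that assumption is wrong. Imputation is
  expected to run per acquisition mode, before correction.

## Problem sizes

The test suite and acceptance script run everything at the preset scales
above (a few hundred samples, 100–500 features), chosen so the full
pipeline — simulation, five corrections, scoring, diagnostics — completes
in well under a minute per scenario while keeping the per-batch sample
counts in the range where the EB shrinkage and bootstrap aggregation
behave as they do at cohort scale.

## Known limitations

* Per-feature OLS with BH adjustment replaces moderated (shrunken-
  variance) test statistics in `differential_analysis`; with very few
  samples per group, moderated statistics would be more powerful.
* The nonparametric ComBat posterior is $O(G^2)$ per batch; for feature
  panels beyond ~10⁴ expect minutes, not seconds.
* `qc_lowess` assumes QC identity across batches (one pooled material);
  surrogate QCs that differ between batches violate the shared-reference
  assumption and will mis-anchor the ratio.
* No probabilistic treatment of left-censoring: imputation precedes
  correction, so heavy censoring biases location estimates low.
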