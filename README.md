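# metabatch

Batch-effect correction and data-driven model selection for large
multi-batch LC–MS metabolomics feature tables.

## The problem

Large metabolomics studies are acquired in many analytical batches over
months. Instrument state drifts within and between batches, so every
feature carries a systematic, non-biological location and scale imprint of
its batch. The standard remedy — periodic injection of pooled QC samples
and a QC-anchored smoother — requires QCs that truly represent the study
samples, and it silently discards any compound that falls below the
detection limit in the pooled QCs. Statistical batch models need no QCs,
but no single model fits every data structure; the practical question is
*which* correction to trust for *this* dataset.

`metabatch` implements a menu of location/scale corrections and a score
that ranks them on the data at hand:

* **ber** — two-stage per-feature least squares: stage 1 removes additive
  batch offsets γ̂\_ig (fitted jointly with any biological covariates under
  a sample-size-weighted sum-to-zero constraint), stage 2 rescales the
  per-batch residual spread ŝ\_ig to the pooled scale. After correction,
  per-batch means and variances are equal by construction.
* **bagged ber** — the same parameters aggregated over a stratified
  within-batch bootstrap (default 150 replicates); the correction is
  applied once with the averaged parameters.
* **ComBat**, parametric and nonparametric — empirical-Bayes shrinkage of
  per-batch location/scale estimates on standardized data,
  Z\_ijg = (Y\_ijg − α̂\_g − X\_j β̂\_g)/σ̂\_g, with Normal / inverse-gamma
  priors (parametric, method-of-moments hyperparameters and a fixed-point
  iteration) or likelihood-weighted posterior means (nonparametric).
* **QC lowess** — the QC-based comparator: a locally weighted drift curve
  through the QC intensities versus injection order, ratio correction to
  the feature's median QC level.

**Model selection.** For each candidate output, the per-feature adjusted
coefficient of determination of intensity on batch,

    adj-R²_g = 1 − (1 − SS_between/SS_total) · (n − 1)/(n − B),

measures how much of feature *g*'s variance batch still explains. A
dataset's score is the maximum over features, clipped to [0, 1]: the worst
surviving batch dependence. Models are ranked ascending — the lower the
score, the better the correction.

The package also ships the surrounding workflow: CSV/TSV readers and
writers, log2 transform, presence filtering, left-censored (half-minimum)
and kNN imputation, PCA / hierarchical-clustering / per-feature
distribution diagnostics, downstream validation statistics (Fisher-z
correlation intervals, covariate-adjusted association scans, two-group
differential analysis with BH control), and a seeded simulator of
multi-batch acquisitions with known ground truth.

## Worked example

Simulate a targeted-cohort-like acquisition (11 batches × 20 plasma
samples, 100 metabolites, bracketing QCs, strong batch effects), then
correct with every model and rank:

```r
library(metabatch)

sim <- simulate_batches(preset_config("targeted_cohort"), seed = 42)
sim$fm
#> feature_matrix: 253 samples x 100 features (log2 scale)
#>   batches: 11 (batch_01, batch_02, ...)
#>   QC samples: 33
#>   missing entries: 0 (0%)

cmp <- compare_models(sim$fm,
                      c("ber", "ber_bagged", "combat_parametric",
                        "combat_nonparametric", "qc_lowess"),
                      seed = 42)
cmp$ranking[, 1:5]
#>   rank                model  score  raw_max mean_adj_r2
#> 1    1                  ber 0.0000 -0.04785    -0.04785
#> 2    2    combat_parametric 0.0000 -0.04733    -0.04764
#> 3    3           ber_bagged 0.0000 -0.04716    -0.04750
#> 4    4            qc_lowess 0.4716  0.47163     0.20996
#> 5    5 combat_nonparametric 0.6533  0.65327     0.02445
#> 6    6                  raw 0.9703  0.97030     0.91388
```

Read: in the raw data, batch explains up to 97% of a feature's variance.
ber and parametric ComBat remove that completely (score 0; the slightly
negative unclipped maxima are the signature of a regression with no
explanatory power left), while the QC-lowess comparator — fitted from only
3 QCs per batch — and nonparametric ComBat leave features with ~47% and
~65% residual batch dependence. `summary(cmp$fits$ber)` prints the
before/after score for a single fit; `plot(cmp)` draws the score bar
panel, `plot(cmp$fits$ber)` the before/after PCA.

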