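---
title: "Marker-distance drug ranking: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Marker-distance drug ranking: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`emdrank` predicts and ranks the anti-proliferative efficacy of drug panels
within individual cancer samples. This vignette is the package's account of
the statistical machinery: the models and their assumptions, every tunable
parameter with its default and rationale, what the synthetic panel generator
does and does not emulate, and the design choices made where the design was
genuinely open.

## 1. The response variable and input normalization

Drug response is the area above the dose-response curve (AAC). `scale_aac()`
min–max scales each cell line's observed responses across its drugs to
`[0, 1]` (0 = no effect, 1 = maximum killing), normalizing for assay
conditions. The scaling axis is a genuine ambiguity — a per-line and a
per-drug normalization both have defensible readings — so the per-line
default carries a `axis = "drug"` switch for sensitivity analysis.
`filter_drugs_by_iqr()` then drops drugs whose across-line interquartile
range (type-7 quantiles) is not strictly greater than 0.15 AAC units:
near-constant response rows cannot support a sensitive/resistant contrast.

Omics matrices (phosphosite, protein or transcript abundances) are averaged
over replicate samples per cell line (`average_replicates()`; an entry is
missing only when missing in every replicate) and then z-scored per feature
(`center_scale_features()`; mean 0, sd 1 with the n−1 denominator over
non-missing entries; zero-variance features are set to 0 and flagged). An
optional `log2(x + 1)` pre-transform is off by default because verification
against external data uses intensity values as provided. Missing abundances
are never imputed; every downstream stage handles them explicitly.

## 2. EMDR discovery

For each drug the observed cell lines are split at the median AAC; lines
exactly at the median go to the sensitive side (a fixed, tested tie rule).
Each side needs at least `min_group_size = 6` observed lines. Both sides are
resampled into `k = 10` leave-one-fold-out subsets (each holding roughly
9/10 of its population — folds this small could not support linear-model
contrasts if the ten groups were disjoint tenths), giving `k × k = 100`
group pairs. A two-sided Welch t-test on the AAC values of each pair screens
out unseparated pairs at `screen_alpha = 0.05`; the consistency denominator
is the number of *retained* pairs, and entries with fewer than
`min_retained = 10` retained pairs are flagged low-support.

Each retained pair is contrasted feature-by-feature with a moderated t-test
(`moderated_ttest()`), authored in-package:

* per feature, `coef = mean(sensitive) − mean(resistant)` with pooled
  variance `s²` on `df = n₁ + n₂ − 2`;
* the prior `(d₀, s₀²)` comes from closed-form method-of-moments on
  `log s²` (digamma/trigamma inversion); `d₀ = ∞` collapses every posterior
  variance to `s₀²` and arises naturally when variances are homogeneous;
* posterior variance `s̃² = (d₀ s₀² + df s²)/(d₀ + df)`, moderated
  `t = coef / (s̃ √(1/n₁ + 1/n₂))` on `d₀ + df` degrees of freedom, BH
  adjustment across features.

The test suite verifies this implementation against `limma::eBayes` and an
independent moment-estimator oracle to 10⁻⁶ relative error. One subtlety:
when all features share an identical `s²`, the estimated prior is the
bias-corrected log-scale mean, `s₀² = s² · exp(log(df/2) − ψ(df/2))`, which
differs from `s²` by a factor that vanishes only as `df → ∞` — so the
moderated t approaches, but does not exactly equal, the pooled t in that
degenerate case (`limma` behaves identically). The exact degeneracy that
*does* hold, and is tested, is `d₀ → 0 ⇒ s̃² = s²`.

A feature becomes a **sensitivity marker** when `coef ≥ +0.8` (normalized
abundance units — the only scale present after z-scoring) with `p < 0.05`
in at least `consistency = 80%` of retained pairs; `coef ≤ −0.8` mirrors
this for **resistance markers**. The within-repeat p-value is the *raw*
moderated p by default (`use_adjusted_p = FALSE`). This was a genuinely open
choice: the procedure's multiple-testing control is the consistency rule
itself — a feature must clear both thresholds in ≥80% of ~100 resampled
contrasts — and per-repeat BH across feature spaces of realistic size
(10³–10⁴ features at panel sizes of 10–25 lines per group) is so
conservative that essentially no feature of moderate effect survives it; the
flag restores the adjusted-p variant for users who want it.

Per-drug seeds are derived by stable string hashing of the master seed and
the drug id (`derive_seed()`), so adding or reordering drugs never perturbs
other drugs' resamples; the whole catalog is bit-reproducible.

## 3. The distance metric D

For drug *d* and sample *b*:

```
D(d, b) = (S_Q2 − R_Q2) + (S_Q3 − R_Q3)
```

with `S_Q2`, `S_Q3` the median and third quartile (type-7) of the
sensitivity-marker values present in the sample and `R_Q2`, `R_Q3` the same
for resistance markers. Higher D means more sensitive. Properties the suite
asserts: adding a constant to a whole profile leaves D unchanged (internal
normalization — no reference sample is needed); swapping the marker sets
negates D; duplicate listings and marker order are irrelevant. Quartiles are
computed over the non-missing marker values only, with a coverage floor of
`min_markers = 5` per side below which the entry is reported missing with a
reason, never silently zeroed — the floor is a package choice, as missing-
marker tolerance needs *some* minimum for a quartile to be meaningful.
Replicates are averaged to cell lines before D is computed.

For modeling, each drug's D values are min–max normalized to `[0, 1]` with
parameters fitted on the *training* cell lines only and stored with the
model; new samples are transformed with the stored parameters and clipped.

## 4. Predictor selection and the model roster

Each candidate drug's D row is Spearman-correlated (average ranks on ties;
two-sided p from the t approximation on n−2 df) with the target drug's
training responses; the target's own D is among the candidates. Selection,
per correlation direction: significant candidates (raw `p < 0.05`) ranked by
`|rho|`, capped at 30; if fewer than 7 are significant, the top 7 by `|rho|`
are taken regardless of significance — the only reading that guarantees the
14-predictor minimum. Ties on `|rho|` break lexicographically by drug id for
determinism. The result is 14–60 predictors whenever each direction offers
at least 7 candidates.

Cell lines are partitioned 0.8/0.2 into training and validation sets,
stratified on quantile bins of the mean AAC (caret's numeric-outcome
behavior). Eight regressors are trained per drug on the normalized D
features:

| name | implementation | grid |
|---|---|---|
| `random_forest` | randomForest | mtry ∈ {√p, p/3}, 500 trees |
| `rule_committee` | xgboost (gradient-boosted trees) | nrounds ∈ {50, 150} × depth ∈ {2, 3}, η = 0.1 |
| `bayes_glm` | glmnet ridge GLM | λ ∈ {0.01, 0.1, 1} |
| `pls` | mixOmics PLS regression | ncomp ∈ 1…min(6, p, n−2) |
| `pcr` | prcomp + lm (in-package) | ncomp ∈ 1…min(6, p, n−2) |
| `svr` | e1071 RBF ε-SVR | cost ∈ {1, 10} |
| `mlp_single` | nnet, one hidden layer | size ∈ {3, 5} × decay ∈ {0.01, 0.1} |
| `mlp_deep` | in-package 2-hidden-layer perceptron (tanh, BFGS, analytic gradients) | decay ∈ {0.01, 0.1}, sizes (8, 4) |

`rule_committee`, `bayes_glm` and `mlp_deep` are documented stand-ins for
rule-based committee regression, Bayesian GLM estimation and deep-learning
regression respectively; the roster contract is the algorithm *family* plus
the shared CV protocol, and the stand-ins are flagged in the run manifest.
The two-layer perceptron is written in-package (with a finite-difference
gradient check in the suite) because no multi-hidden-layer regressor exists
in the dependency set. Grids are deliberately small (≤ 12 points): with
10–40 training lines per drug, finer grids only overfit the resampling.

Hyperparameters minimize mean RMSE over repeated 10-fold CV (3 repeats, 30
resamples) — except `pls`/`pcr`, tuned by leave-one-out CV — followed by a
final refit on all training lines. A failing algorithm is marked unavailable
for that drug without affecting the others. Predictions are clipped to
`[0, 1]`; the consensus prediction is the unweighted mean of the random
forest, PCR and PLS predictions, requiring at least two available members.
`stratify_by_mean_prediction()` labels samples above the mean predicted AAC
"high" — the cutoff used to split cohorts for survival comparisons.

**Leakage guard.** EMDR discovery, predictor selection, D normalization and
model fitting see training cell lines only. The pipeline records the sample
ids each stage consumed in its manifest and aborts if any validation line
appears (`assert_no_leakage()`); the suite asserts this end to end.

## 5. Evaluation metrics

Per held-out sample: Spearman rho with BH-adjusted q across samples, RMSE
and MSE; per (sample, drug): absolute error and rank displacement
`|rank_pred − rank_meas|` (descending AAC, average ranks on ties). Global
proportions within absolute-error cutoffs {0.05, 0.1, 0.15, 0.25} and
rank-displacement cutoffs {20, 50} (strict `<`), plus the same restricted to
each sample's top-20 drugs. The top-20 subset anchors on *measured* ranks by
default (the evaluation compares against observed rankings); a flag switches
to predicted-rank anchoring, since either reading is defensible.

## 6. Enrichment and drug similarity

Marker-set over-representation uses the ratio `[a/b]/[c/d]` (a = markers in
the set, b = markers, c = background features in the set, d = background
size) with an upper-tail hypergeometric p (verified against exhaustive
enumeration for all backgrounds ≤ 25) and BH adjustment across sets. The
background is the full feature universe of the discovery matrix; sets
smaller than 3 after background intersection are skipped. Delta enrichment
(sensitivity ratio − resistance ratio per set) profiles a drug's mode of
action; a side with no computable enrichment contributes ratio 0, flagged.
Drug–drug similarity is the pairwise Pearson correlation of
delta-enrichment vectors (a flag allows side-specific vectors, as the
underlying definition is ambiguous); the off-diagonal correlations are
rescaled to median 0 / sd 1 and each pair's p-value is a one-sample t-test
of the scaled-score distribution against that pair's score.

## 7. The synthetic panel generator

`generate_panel()` creates panels with known ground truth; its defaults are
the package's study conditions, fixed once:

* per drug and cell line, a latent sensitivity `s ∈ [0, 1]` equal to the
  AAC. `s` mixes a cluster-shared and an independent uniform component
  (weight 0.5, giving within-cluster response correlation ≈ 0.5) and is then
  rank-transformed per drug to an exact uniform grid — the uniform marginal
  keeps median splits balanced by construction;
* planted sensitivity markers with mean abundance `Δ (s − 0.5)` per cell
  line, resistance markers with the negated slope, disjoint per-drug blocks,
  all remaining features pure noise. Every marker follows its own drug's
  latent; cluster structure enters through the latent correlation, which is
  what induces the cross-drug D correlations predictor selection exploits;
* `n_replicates = 3` replicate measurements with `N(0, noise_sd²)` noise and
  5% missingness.

`reference_settings()` fixes the canonical panel: 24 cell lines × 3
replicates, 1000 features, 24 drugs in 6 clusters, 20 + 20 markers per drug,
`Δ = 2`, `noise_sd = 1`, seed 17. These sizes keep the full test suite
around two minutes on one CPU while leaving 10–12 lines per split side — the
small end of realistic panel sizes.

**What the generator does not emulate**, and hence what passing tests do not
show about real data:

* *Concentrated response distributions.* Real AAC panels pile up at low
  response; the uniform latent has per-drug sd 0.29. Absolute-error metrics
  are therefore pessimistic here: with ~20 training lines, every roster
  member attains held-out RMSE ≈ 0.16–0.19 on uniform targets, so
  error-bin proportions (e.g. the share of predictions within 0.15 AAC)
  look far worse than on real screens even though rank recovery is strong.
  Rank-based metrics (Spearman, rank displacement) are the meaningful
  quantities at these conditions.
* *Feature-marker cross-talk by construction.* Because drugs' latents
  correlate (by cluster design, and by chance in a 24-line panel), markers
  planted for one drug genuinely co-vary with another drug's response. When
  marker discovery is scored strictly against each drug's *own* planted
  set, such calls count as false positives although they carry true signal
  — an oracle thresholding the true realized group differences would call
  them too. Precision against pure-noise features is the discriminating
  measure (≈ 0.99 at reference settings); strict per-drug precision
  conflates discovery quality with the panel's latent correlation.
* *Mass-spectrometric intensity structure* (dynamic range, peptide-level
  correlation, intensity-dependent missingness — missingness here is
  uniform at random).
* *The z-scale null spread.* After per-feature z-scoring, a null feature's
  group-mean contrast has standard error √(2/n) per side regardless of the
  underlying noise level; at 12 + 12 lines that is ≈ 0.41, so the ±0.8 fold
  rule with 80% consistency admits roughly 1.5–2.5% of null features. Null
  calibration improves with panel size, not with the noise level.

## 8. Numerical conventions and degenerate inputs

* Quantiles: type-7 linear interpolation everywhere; sd uses n−1.
* Median-split ties → sensitive group; `|rho|` ties → lexicographic drug id;
  ranking ties → average ranks (metrics) or lexicographic (ordered lists).
* Zero-variance features: z-scored to 0 and flagged; excluded from the
  variance-prior moment estimation but still given a posterior variance.
* Constant D rows: excluded from normalization and modeling, with a warning;
  constant AAC columns: an error naming the cell line (degenerate scaling).
* Welch screens between zero-variance groups: identical constants give
  p = 1, separated constants p = 0 (the limit of the statistic).
* All randomness flows from one master seed through `derive_seed()` string
  hashing (< 2³¹); two runs with the same configuration and seed are
  bit-identical on one machine.
* Out-of-range predictions and normalized D values are clipped to `[0, 1]`.

## 9. Known limitations

* With ~20 training lines per drug the regression stage is shrinkage-bound;
  absolute calibration (as opposed to ranking) needs larger panels.
* The EMDR fold threshold (±0.8 normalized units) is a fixed constant
  inherited from the method definition, not adaptive to panel size; at small
  n it trades null-feature admission against marker recall (section 7).
* The deep-learning member is a small two-layer perceptron — a documented
  approximation of the original approach's deep models, adequate for 14–60
  features but not a substitute for large-scale architectures.
* Transcriptome-specific behavior is untested here; the synthetic generator
  emulates the abundance-matrix interface, not RNA-seq count structure.

## 10. Session

```{r}
sessionInfo()
```
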