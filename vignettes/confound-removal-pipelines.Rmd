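---
title: "Confound removal pipelines: model, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Confound removal pipelines: model, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deconfound)
```

## The problem

A confound is a variable associated with both the features and the
prediction target. The motivating case is sex decoding from resting-state
fMRI features: brain size differs strongly between sexes and is encoded in
imaging features, so a decoder can achieve high accuracy by reading brain
size rather than any sex-specific functional signal. Unless the confounding
signal is removed, both of the usual goals of a decoding analysis —
estimating generalization performance and identifying predictive features —
are biased.

`deconfound` implements the standard remedy, per-feature linear confound
regression, as a fit/apply operator, and everything needed to study how the
*placement* of that operator inside a machine-learning pipeline changes the
answers: whole-data versus cross-validated removal, interaction with z-score
normalization, residual-confounding audits, and four strategies for carrying
removal over to out-of-sample (OOS) data.

## The removal operator

Given features $X \in \mathbb{R}^{n \times p}$ and confounds
$Z \in \mathbb{R}^{n \times c}$, a linear model is fitted to each feature
separately with the confounds (plus intercept) as predictors,

$$\hat\beta_j = \arg\min_\beta \lVert X_{\cdot j} - [1\,|\,Z]\,\beta \rVert^2,$$

and the residuals $X_{\cdot j} - [1\,|\,Z]\hat\beta_j$ become the
"confound-removed" features (`fit_confound_model()` /
`remove_confounds()`). On the fitting sample the residuals are exactly
orthogonal to every confound column and to the intercept; applied to rows
outside the fitting sample they are generically not — that gap is precisely
what the deployment experiments measure.

Numerical choices: the intercept is always included (residuals must be
mean-free); confounds are not standardized before fitting, because OLS
residuals are invariant to affine reparameterization of the confound
columns; a rank-deficient confound design produces a warning and the
minimum-norm (pseudo-inverse) solution instead of an error, so degenerate
confound tables do not crash a pipeline mid-run.

## Whole-data vs cross-validated removal

Two schemes place this operator relative to the cross-validation (CV) loop:

* **WDCR** (whole-data confound regression): fit and apply on *all* rows
  before splitting. Information from validation rows leaks into the removal
  step; this leakage is the scheme's defining property, not an accident.
* **CVCR** (cross-validated confound regression): within each CV fold, fit
  on the training rows only and apply to both training and validation rows.
  No statistic ever touches a validation row (a property the test suite
  checks bitwise).

Combined with z-scoring — none (NZ), after removal (ZAC), before removal
(ZBC), and plain z-scoring for the no-removal arm — exactly eight pipelines
are constructible (`pipeline_spec()`, `all_pipelines()`).

Two placement conventions were genuinely open and are fixed as follows. For
WDCR pipelines the z-scoring is also fitted whole-data (ZBC before the
whole-data removal, ZAC on the whole-data residuals), keeping the whole-data
arm wholly pre-CV so that its leakage is uniform rather than mixed. For the
no-removal NCR-Z pipeline the z-score is fitted within the training fold,
since the leakage under study is specific to the confound-removal step and
plain normalization is conventionally fold-consistent.

ZBC and ZAC are algebraically near-equivalent: residualization is linear and
scale-equivariant per column, so z-before and z-after residual matrices are
column-wise proportional with positive factors. The package's tests verify
both this identity (cosine similarity 1 within 1e-8) and its consequence,
CV AUC gaps below 0.03 between the two placements.

## Decoders

Two linear regression models are used as continuous scorers for the binary
target, encoded $-1/+1$ with hard labels from thresholding the score at 0
(the midpoint of the encoding — the encoding and threshold are package
conventions, fixed for reproducibility):

* **Ridge** (`fit_ridge()`): intercept-unpenalized,
  $w = (\tilde X^\top \tilde X + \lambda I)^{-1}\tilde X^\top \tilde y$ on
  centered data, solved exactly through a symmetric eigendecomposition
  (the dual $n \times n$ system when $p > n$; minimum-norm at
  $\lambda = 0$). The eigendecomposition is reused across the whole
  $\lambda$ grid during tuning, so a grid search costs little more than one
  fit.
* **PLS1** (`fit_pls()`): latent components extracted to maximize feature–
  target covariance by the standard deflation algorithm (NIPALS-equivalent
  for a single response), folded into one weight vector plus intercept. At
  full rank its predictions coincide with OLS — one of the oracle
  identities in the test suite, alongside a literal textbook NIPALS
  implementation kept independent of the production path.

Hyperparameters (λ, or the number of components) are tuned by stratified
inner CV maximizing mean validation AUC (`tune_hyperparameter()`); exact
ties resolve to the stronger regularization. Defaults — λ grid
$10^{-3}, \dots, 10^3$, components $1..\min(20, p, n-2)$, 5 inner folds —
are package conventions; none of these settings is prescribed by the
problem itself.

## Evaluation and feature weights

`run_pipeline_cv()` runs one pipeline under repeated stratified k-fold CV
(default 10×10), reporting per-fold AUC (Mann–Whitney rank form, ties worth
one half), F1 and balanced accuracy, plus an aggregated importance per
feature: within each fold's fitted decoder the weight vector is z-scored
across features, absolute values taken, then averaged across folds
(`aggregate_feature_weights()`; an alternative reading — z-scoring each
feature across runs — exists, and the within-run-across-features form was
chosen as the more direct reading of the standard recipe).
Fold assignment is stratified by class (balanced accuracy and F1 are
unstable under class-imbalanced folds) and every (repeat, fold) derives its
RNG stream from (seed, repeat, fold), so runs are reproducible and
individual folds can be recomputed in isolation.

## Diagnostics

Whether removal *worked* is an empirical question, answered two ways
(`residual_diagnostics()`):

* per-feature Pearson correlation of residuals with each confound, p-values
  from the t-transform (raw and Bonferroni columns are both reported; no
  correction is applied by default);
* a multivariate audit: regress the confound on all residual features;
  in-sample after removal $r^2 = 0$ by orthogonality and the adjusted value
  $1 - (n-1)/(n-p-1)$ is *negative* for every $p \ge 1$ — the signature of
  residuals carrying no confound information. When $p \ge n - 1$ the fit is
  minimum-norm and flagged; when $n - p - 1 \le 0$ the adjusted value is
  reported as undefined rather than extrapolated, because the formula's
  denominator is non-positive and the audit is not interpretable in that
  regime.

`group_difference_test()` (Welch's two-sample t-test — the unequal-variance
form is the safer default when only "a t-test" is conventional) establishes
a variable as a confound in the first place, e.g. the sex difference in
brain size.

## Deployment: four OOS strategies

`finalize_model()` turns a trained pipeline into a single deployable bundle:
all statistics fitted on the full training set, hyperparameter tuned by
inner CV, decoder fitted on the transformed training data. For a CVCR
pipeline the deployable confound model is necessarily fitted on the full
training set — numerically identical to WDCR-on-train. This is deliberate
and worth stating prominently: a deployed model needs *one* transform, and
the WDCR/CVCR distinction lives in how generalization is *estimated*, not
in the deployed artifact.

Four ways to handle confounds in OOS data are implemented:

1. **train-to-test** (`oos_train_to_test()`): apply the train-fitted removal
   to OOS rows — the standard route. OOS residuals are generically not
   orthogonal to OOS confounds; the attached diagnostics quantify this.
2. **test WDCR** (`oos_self_removal(..., "WDCR")`): refit removal on the
   whole OOS sample; exactly orthogonal in-sample there.
3. **test CVCR** (`oos_self_removal(..., "CVCR")`): refit per OOS fold,
   residuals retained (supports the leave-one-out limit).
4. **combined WDCR** (`oos_combined_wdcr()`): refit on train+OOS
   concatenated, re-split into the *original* membership (no reshuffling —
   the purpose is to evaluate the original OOS cohort), decoder re-fitted
   and re-tuned on the train part. Orthogonality then holds over the
   concatenation but, under distribution shift, *not* within each part —
   diagnostics are therefore reported per part.

Methods 2–4 require an OOS sample large enough to refit on; with train-side
z-scoring the train parameters are applied in the pipeline's order around
the refitted removal.

## The synthetic generator

Real neuroimaging cohorts of this kind are access-restricted, so the
package ships a generator of confounded datasets with known ground truth
(`generate_confounded_dataset()`): a binary target with fixed class counts;
Gaussian confounds, the first ("size"-like) shifted between classes by a
configurable standardized mean difference, the second ("age"-like)
independent of the target by default (optional coupling via
`secondary_class_shift`); features built as
`direct_effect · (±1 target) + loadings · confounds + noise`, with
per-feature roles (signal-only / confound-only / mixed / null) apportioned
by largest-remainder rounding and recorded as metadata. The ±1 class coding
and Gaussian confounds are the simplest family in which effect sizes are
controllable in SD units. Structural parameters (roles, loading signs) are
derived from the seed separately from the data draw, so an OOS cohort from
`generate_shifted_oos()` shares its base sample's architecture while
confound means/SDs, confound→feature coefficient strength, feature scale
and class–confound coupling shift per `shift_config()`.

Defaults describe the standard study conditions used throughout the tests:
n = 300 samples, p = 160 features (the ReHo-like dimensionality; FC-like
experiments use p in the thousands), two confounds, confound class shift
1.5 (large enough that the confound's two-sample t-test rejects at
p < 0.001 at this n, the hallmark pattern), direct effect 0.3, confound
effect 1, noise SD 1, role fractions 0.2/0.3/0.2/0.3. The effect sizes were
chosen once for testability — clear signal above noise at desk-scale n —
not calibrated to any particular cohort; per-feature feature–confound
correlations (~0.7 for confound-carrying features) are stronger than
typically observed in real imaging features (~0.2–0.4), which makes
removal-related phenomena *more* pronounced here than in real data (see
Limitations). The generator deliberately omits temporal autocorrelation,
motion artifacts, site effects and atlas geometry; toy ROI time-series for
exercising the feature-extraction formulas come from
`generate_roi_timeseries()` (shared latent per ROI plus voxel noise).

## Feature extraction

From ROI-grouped voxel time-series the two canonical feature spaces are
computed: regional homogeneity — Kendall's coefficient of concordance
$W = 12S / (K^2(T^3 - T) - K\,C)$ across the $K$ voxel series of an ROI,
with average ranks and the standard tie-correction term $C$ (the
tie-corrected variant is a choice; the uncorrected form is recovered when
no ties occur) — and functional connectivity: Pearson correlations between
ROI-averaged series, Fisher z-transformed (`atanh`, with $|r| = 1$ clipped
to $1 - 10^{-15}$ so outputs stay finite), strict lower triangle vectorized
in row-major $i > j$ order (the order itself is a convention and is
documented in `vectorize_lower()`; 160 ROIs give the canonical 12,720
features).

## What the tests do and do not show

The test suite verifies the machinery against independent oracles
(projection-matrix residuals, brute-force AUC, textbook NIPALS, glmnet,
pROC, permutation nulls) and reproduces the qualitative phenomena on
synthetic data at reduced scale: confound-driven decoding (~0.85 AUC raw)
collapsing to chance after cross-validated removal; the CVCR generalization
estimate landing closer to a deployed model's large-sample OOS AUC than the
WDCR estimate in the large majority of seeds (20 seeds at n = 300,
p = 100, with 5-fold × 2-repeat outer CV and ridge decoding — sizes chosen
to keep the full suite fast on a laptop); z-placement indifference; and the
deployment orthogonality patterns. Passing these on Gaussian synthetic data
says the *machinery* is correct and the *mechanisms* behave as described;
it does not certify effect sizes on real imaging cohorts, where confound
coupling is weaker, heavier-tailed and structured.

## Known limitations

* Removal is linear and univariate per feature. Nonlinear or joint
  multivariate confound effects are out of scope (the multivariate audit
  *detects* linear multivariate leftovers but nothing removes them).
* Under the strong feature–confound coupling of the default generator,
  whole-data removal does not merely fall to chance: its CV AUC sits
  slightly *below* 0.5 (~0.39 at the standard conditions). Whole-data
  residualization pins each feature's total sample association with the
  target's confound-orthogonal component near zero, so chance correlation
  present in the training folds is exactly compensated in the validation
  folds, and a decoder aligned with the training folds scores
  anti-correlated out-of-fold. The effect is implementation-independent
  (reproducible with an unrelated ridge/CV stack) and shrinks with weaker
  confound coupling; it is the extreme form of whole-data removal's
  pessimism.
* Only two decoders are provided, both linear; the threshold-at-0
  convention makes F1/balanced accuracy depend on the ±1 encoding.
* The generator's Gaussianity and independence structure are idealized;
  none of the fMRI preprocessing chain (denoising, normalization, atlas
  handling) is modelled or implemented.
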