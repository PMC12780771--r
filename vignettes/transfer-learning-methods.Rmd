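---
title: "Transfer learning for probable-dementia classification: models, design choices, and what the synthetic studies show"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transfer learning for probable-dementia classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The estimation problem

Large community surveys of older adults carry brief cognitive batteries
from which *algorithmic* dementia probabilities have been derived; these
are plentiful but imprecise. Much smaller sub-studies administer in-depth
assessments that yield a near gold-standard dementia classification, but
at sample sizes — a few hundred participants in the non-Hispanic Black
and Hispanic strata — too small to fit a stable group-specific model on
their own. `demtransfer` implements a two-step transfer-learning
estimator that borrows strength from the large, imprecisely labelled
*source* cohort while letting the small, well-labelled *target* cohort
correct the borrowed coefficients where they genuinely differ.

**Step 1 (source knowledge).** The source's continuous dementia
probability is dichotomized at a threshold (0.5 by default; 0.25 and
0.75 are accepted) and a logistic LASSO is fitted:

$$\hat\beta_{src} = \arg\min_\beta\; \tfrac1{n_{src}}\textstyle\sum_i
\ell(\beta; x_i, y^{src}_i) + \lambda\,\|\beta\|_1 ,$$

with $\ell$ the logistic negative log-likelihood and $\lambda$ chosen by
stratified 10-fold cross-validation.

**Step 2 (deviation correction).** On the target cohort the coefficients
are refitted under an L1 penalty on the *deviation* from the source
estimate:

$$\hat\beta_{TL} = \arg\min_\beta\; \tfrac1{n_{tgt}}\textstyle\sum_i
\ell(\beta; x_i, y^{tgt}_i) + \lambda\,\|\beta - \hat\beta_{src}\|_1 .$$

When the two cohorts' predictor-outcome associations differ in only a
few coordinates (a *sparse deviation*), this estimator trades a small,
sparse correction against the variance of a target-only fit — the
deviation–variance trade-off that motivates transfer. The fitted
deviation $\hat\delta = \hat\beta_{TL} - \hat\beta_{src}$ is itself the
object of the deviation analysis below.

Model development is stratified: one model per race/ethnicity stratum
among self-respondents, one pooled model for proxy respondents (whose
cognitive state is measured by the informant-rated IQCODE instead of the
direct battery).

## The solver

Both steps reduce to one primitive: L1-penalized logistic regression
with an optional *penalty center* $c$, solved in compiled code by
reparameterizing $\delta = \beta - c$ and minimizing a standard L1
logistic objective with fixed offset $Xc$. The algorithm is proximal
Newton: an IRLS quadratic approximation, cyclic coordinate descent with
soft-thresholding on the quadratic, and a backtracking line search on
the exact objective, so the recorded objective trace is non-increasing
by construction. Coordinates are screened by the gradient at the warm
start; the screen is exact because the full KKT conditions are
re-checked at the solution and violators re-enter. The intercept — and
hence the intercept's deviation — is never penalized.

Numerical choices that matter:

* convergence: relative objective change below `tol` (default `1e-8`
  for single fits; cross-validation paths use `1e-5` and the pipeline's
  final cohort-scale fits `1e-6`, which changes selected penalties and
  coefficients by less than the bootstrap noise while cutting cost
  several-fold);
* fitted probabilities are clamped to `[1e-5, 1 - 1e-5]` inside IRLS
  (the glmnet convention), which keeps working residuals bounded on
  quasi-separable data;
* the penalty grid is 100 log-spaced values from the data-derived
  $\lambda_{max}$ (smallest penalty with an all-zero penalized part)
  down to $10^{-4}\lambda_{max}$; exact ties in the cross-validation
  arg-min break toward the larger, more regularized value;
* cross-validation folds are stratified by outcome; a rarer class with
  fewer than K members reduces K with a warning, a single-class outcome
  is an error;
* paths stop early once the training fit is saturated (99.9% of null
  deviance) or flat (three consecutive steps improving the null-scaled
  deviance by less than $10^{-5}$), and a fold's path additionally stops
  once its held-out loss is clearly past its minimum — cut-off penalties
  inherit the last loss, which can never become the arg-min, so the
  selection is unchanged;
* cold fits at small penalties run a short internal homotopy (8-step
  decreasing-penalty warm-up) before the final solve.

Cross-validation loss is the held-out mean negative log-likelihood, not
misclassification, matching the fitting objective. Continuous predictors
can be standardized with training-set statistics (`standardize` in the
encoding), but the default is off: the predictors here are dummies and
bounded scores on comparable scales, and an unstandardized fit keeps
source and target coefficients directly comparable, which the deviation
penalty requires.

## Negative-transfer guard

Borrowing from an unrelated source can hurt. Before fitting, the
pipeline can split the target into K stratified folds and compare, per
fold, a target-only LASSO against a transfer fit centered at the
full-source estimate, both tuned on the training folds and scored on the
held-out fold. The source is declared transferable when the mean
held-out transfer loss does not exceed the target-only mean by more than
`threshold_c` (default 1) fold-SDs of the target-only loss. When the
guard trips, the pipeline's "transfer" model silently falls back to the
target-only procedure for that cell. Because the deviation penalty is
itself cross-validated, mild source misspecification is absorbed rather
than flagged; the guard fires on gross, dense discrepancies — which is
the failure mode that matters.

## Internal validation and deviation analysis

Following the internal-validation protocol for small samples, each model
is validated by bootstrap: B times (1000 in the full protocol; desk
runs use 25–200), resample the target with replacement, rerun the
*entire* procedure — encoding statistics, penalty cross-validation,
transfer fit — on the resample, and score on the original, untouched
target. Reported metrics are the across-run mean with the empirical
across-run standard deviation. Five measures are computed: Brier score,
calibration intercept (offset recalibration with slope fixed at 1),
calibration slope (free logit recalibration), AUC (rank/Mann–Whitney
form, ties one half), and AUPRC (non-interpolated average precision;
trapezoidal interpolation overstates PR area, so it is not used).
Predictions are clipped to `[1e-6, 1 - 1e-6]` before the logit, and
the calibration intercept is computed by monotone 1-D root finding of
its score equation (equivalent to the offset logistic regression, but
stable under extreme offsets). Resamples with fewer than two rows of
either outcome class — too degenerate to stratify folds — are redrawn
and counted.

The per-run transfer fits double as the deviation archive: a predictor
is *flagged* when its fitted deviation is nonzero (|δ̂| > 1e-10, the
solver-noise tolerance) in at least half the runs **and** the 95%
percentile interval of δ̂ over the runs in which it was detected
excludes zero. The interval is restricted to detected runs on purpose:
under L1 selection the all-runs interval of any predictor detected in
fewer than 97.5% of runs touches zero exactly, which would make the
detection-frequency condition redundant; the two conditions are kept
independent — consistency of selection, and consistency of the selected
sign and size. A per-run confidence interval would be the other reading
of "significant", but it requires inferential machinery the procedure
does not otherwise use. Flagged deviations are reported sorted by mean
magnitude and plotted as horizontal bars per stratum.

One more subtlety matters here: bootstrap resamples duplicate rows, and
a duplicate appearing in both a training and a held-out fold lets the
cross-validation memorize it, driving the selected penalty toward zero
and the fitted deviations to absurd magnitudes. Fold assignment is
therefore grouped by original row identity (`groups` in
`cv_select_lambda()`): all copies of a row share a fold.

Two reading notes on the bootstrap. First, the "asymptotic standard
deviation" reported with each metric is the empirical SD across
bootstrap runs. Second, when encoding is deterministic (no
standardization), the source-side fit does not depend on the target
resample, so the pipeline computes it once per cell and reuses it across
runs — bit-identical to recomputing it, at a fraction of the cost. With
standardization on, it is recomputed inside every run.

## The synthetic cohort generator

No public microdata accompany the real cohorts, so the package ships a
generator that emulates their *structure*, and every downstream claim is
tested against it:

* **Predictors.** Age in five bands (70–74 … >89) and education in five
  bands (<6 … >12 years), drawn categorically with stratum-specific
  education distributions; sex; eight bounded cognitive items (date
  orientation 0–4, immediate/delayed recall 0–10, serial-7 0–5, backward
  counting and three naming items binary) drawn as binomials whose
  success probabilities carry stratum-specific gradients; ADL/IADL
  counts 0–5; continuous change scores; optional filler score columns to
  reach a configured dimension. A per-row latent ability shifts all
  cognitive items (loading 0.7 on the logit scale) and the functional
  limitations (negative loading), reproducing the within-person
  correlation of real batteries — this correlation is what makes forest
  imputation outperform mean imputation, and it raises the realism of
  the covariance structure the LASSO faces.
* **Outcomes.** Per stratum, a sparse true coefficient vector (each
  active effect a standardized magnitude drawn once from
  Unif(0.3, 0.7)) with the intercept calibrated by bisection on a large
  probe sample so the expected target prevalence hits the goal (default
  0.12, matching roughly 293 dementia cases in 2388). The target outcome
  is Bernoulli in that model. The source carries a *probability*:
  sigmoid of the source linear predictor plus logit-scale noise.
* **Source imprecision.** The source coefficient vector is the target's
  plus a sparse deviation: `sparsity_delta` coordinates at exactly the
  per-stratum magnitude (defaults 0.8/0.5/0.2 for Black/Hispanic/White,
  preserving the qualitative ordering of observed deviations), random
  signs. Deviation positions are drawn among the high-information
  quantitative items (recall-type 0-10 scores, probe SD at least 1.5) —
  the region where observed cohort deviations concentrate, and the only
  region where a fixed-magnitude coefficient shift is identifiable at
  the target sizes the shipped experiments use: a 0.5 shift on a rare
  band dummy moves the likelihood too little for any detector. The source *intercept* absorbs the mean shift `-δ'x̄` so
  deviations change associations rather than the base rate. The random
  error is drawn from a **logistic** distribution (scale
  `source_noise_sd`, default 1). This choice is deliberate: with
  logistic noise, the dichotomized source label follows a logistic model
  in the predictors *exactly*, so the source LASSO is consistent for the
  source coefficients — which is precisely the premise of the transfer
  step. Gaussian noise would make the dichotomized label probit-like and
  the source estimate a rescaling of the truth, silently contaminating
  every coordinate of the deviation.
* **Modes and missingness.** A configurable fraction of rows (default
  6%) are proxy respondents: their cognitive items are structurally
  not-applicable and an informative IQCODE (0–5, generated from the
  row's true linear predictor) replaces them. Missingness is injected
  MCAR or MAR (masking probability increasing over age bands with
  multipliers 0.4–1.6, mean 1); outcome, stratum and the age band itself
  are never masked.

What the generator does **not** emulate: survey weights, the real
marginal distributions of items, longitudinal wave linkage (change
scores are emitted directly), measurement error in the target label, and
within-stratum heterogeneity. Tests passing on this generator therefore
demonstrate that the machinery recovers planted structure under the
stated assumptions — not that the real cohorts satisfy those
assumptions.

## Missing-value imputation

Following the study design, imputation runs separately within
self-respondent and proxy-respondent subsets, each on its own predictor
set, so the modes never inform each other. The default strategy chains
random-forest regressions/classifications over the incomplete columns
(initialized with mean/mode fills, visiting columns by increasing
missingness), stopping when the change in imputed values between sweeps
stops decreasing — the previous sweep's values are kept — with a cap of
10 sweeps. A plain mean/mode strategy is available as a fallback and as
the comparison baseline. Imputed bounded columns are rounded and clipped
back to their declared ranges. Exact numerical replication of any
specific imputation package is a non-goal; the stopping rule mirrors the
convention of chained-forest imputation.

## Scale of the shipped experiments

The full protocol (B = 1000 bootstrap runs on cohorts of 6630/2388) is
what the package defaults encode. The test-suite and acceptance-script
experiments run the same machinery at reduced scale, chosen so each
study still has the qualitative regime that matters (n_source ≫
n_target, sparse deviations, small minority strata): transfer-benefit
replicates at n_source = 5000, n_target = 200, p = 50; deviation
recovery at B = 200, n_target = 300; the guard at dense deviations of
magnitude 1; the stratified study in the acceptance script at
n_source = 3000, n_target = 900, B = 25. The vignette states these as
the package's chosen experiment sizes; they are not parameters of the
method.

## Known limitations

* Single-source transfer only; logistic link only (the original probit
  algorithm is emulated, not reimplemented).
* The guard compares fold means with an SD-based slack; it is
  insensitive to mild, dense misspecification by design.
* Bootstrap SDs are empirical across-run SDs, not optimism-corrected
  estimates.
* The deviation flag rule is selection-based; no post-selection
  inference correction is applied. At a few hundred target rows the
  bootstrap conditions on a single target draw whose sampling noise both
  masks true deviations and creates consistently detected spurious ones,
  so per-coordinate detection is reliable only for deviations well above
  that noise floor; at the cohort sizes the defaults encode it is well
  powered.
* With `standardize = TRUE` the bootstrap recomputes the source fit per
  run, which is substantially slower.
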