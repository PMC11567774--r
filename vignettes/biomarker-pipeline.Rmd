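---
title: "Constructing and validating parcellation-based biomarkers of synesthesia"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constructing and validating parcellation-based biomarkers of synesthesia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(synmark)
```

`synmark` implements a multivariate biomarker pipeline for distinguishing
synesthetes from controls using HCP-style cortical parcellations. This
vignette explains the models and procedures it implements, the choices
that were genuinely open and how they were made, what the synthetic
generator does and does not emulate, and the scales at which the test
suite exercises everything.

## The analysis in one paragraph

Per subject, the pipeline receives parcel-level structural maps (surface
area, cortical thickness, intracortical myelin over 360 parcels),
34 subcortical and other volumes, global scalars (eTIV, total surface
area, sex, age), and optionally a resting-state parcel × time matrix.
From these it builds thirteen feature sets ("biomarkers"), harmonizes the
raw measures across acquisition batches with empirical-Bayes ComBat, and
asks, for each biomarker, whether a cross-validated random-forest
classifier separates cases from controls better than a permutation-null
distribution obtained by re-running the identical protocol on shuffled
group labels. Mass-univariate t maps with FDR control, an AUC↔Cohen's d
calculus, a bias-corrected Mahalanobis D, and a noncentral-t power solver
provide the accompanying effect-size language.

## The synthetic-cohort generator

The real cohorts are access-restricted, so the package generates cohorts
with the statistical structure the analysis assumes. The generator is a
first-class, tested module — the conditions it encodes are the study
design the pipeline validates:

* **Sample sizes.** Defaults are 102 cases and 650 controls drawn from
  four batches (300/300/25/25): two large public sources plus two small
  local ones. Cases sit in one (local) batch by default; `case_batch =
  "spread"` distributes them evenly when a test must separate site
  effects from the group contrast (see *Harmonization* below).
* **Structural measures.** Per-parcel Gaussians. Parcel baseline means
  are drawn once per cohort (area 300–700 mm², thickness 2–3 mm, myelin
  T1w/T2w 1.3–1.7, volumes log-uniform 0.5–60 cm³) with residual SDs
  expressed as a fraction of the parcel mean (area 10%, thickness 5%,
  myelin 6%, volumes 12%, eTIV 10%). Group effects are *planted* as mean
  shifts of configurable Cohen's d on chosen parcels, so parameter
  recovery has an exact target. Gaussianity is deliberate: what is under
  test is the calibration of t statistics, correlations and classifiers,
  not distributional realism.
* **Intracranial volume.** eTIV is shifted in cases by `etiv_effect_d`
  (the study direction is negative ≈ −0.32) while global surface area
  remains the exact parcel-area sum, reproducing the smaller-skull /
  non-scaled-cortex configuration whose ratio (cm²/cm³) separates groups.
* **Thickness coupling.** Thickness follows a one-factor model
  `x = μ + σ(√ρ·f + √(1−ρ)·ε)` with inter-parcel correlation
  ρ = `base_coupling` (0.2) raised by `coupling_boost` in cases — the
  generative counterpart of higher inter-regional structural covariance
  in synesthetes.
* **Functional connectomes.** Time series are drawn from a group template
  built as a 5-block stochastic-block correlation matrix with 10% hub
  parcels whose couplings are doubled (ridge-adjusted to stay positive
  definite). The case template is shrunk toward uniform connectivity by
  `hub_flattening` ∈ [0, 1], which produces both signatures the analysis
  looks for: a narrower edge-weight distribution in cases and a negative
  correlation between control centrality and the group difference in
  centrality.
* **Site effects.** Pure location/scale per measure per batch, applied
  last — exactly the model family ComBat removes. Site effects are
  applied to the five structural measures; raw time series are left
  unperturbed, and harmonization of connectivity features is exercised by
  injecting effects at the feature level in tests.
* **Number of types.** Many synesthetes report several types; verified
  cohorts are dominated by multi-type individuals. Types are drawn with
  P(3+ types) ≈ 0.65, which makes the staged 25/25/52 split feasible with
  very high probability at 102 cases. (A steeply decaying "mostly
  one-type" distribution would contradict both the staged split's
  requirement of ≥ 50 multi-type cases and the type counts actual
  cohorts report.) With `types_scale_effects = TRUE`, each case's planted
  shifts scale with `n_types / 3`, giving the vote-share–types relation
  seen in real data. Ages are uniform 18–65 and sex is Bernoulli (75%
  female by default): covariates must exist for harmonization, but their
  realism is irrelevant to what is tested.

What the generator does **not** emulate: BOLD autocorrelation, motion,
vertex-level surface geometry, non-Gaussian tails, or correlated planted
effects across measures. Passing tests therefore certify the machinery —
calibration, leakage-safety, parameter recovery under the assumed model —
not performance on real scanners.

## Harmonization (ComBat)

`combat_fit()` implements the canonical parametric empirical-Bayes
location/scale model: feature-wise standardization after regressing out
covariates and batch means; per-batch moment estimates of additive (γ)
and multiplicative (δ²) effects; a Normal prior on γ and an Inverse-Gamma
prior on δ², hyper-parameters estimated across features by method of
moments, posteriors solved by the standard fixed-point iteration
(tolerance 1e-6, at most 500 iterations). Within-batch variances use the
1/n (maximum-likelihood) denominator so that a single-batch fit returns
its input unchanged — a convenient fixed point that differs from other
implementations only at O(1/n); agreement with `sva::ComBat` is verified
in the test suite.

Two design points deserve emphasis:

* **Fit/apply separation.** The model stores α, β, γ*, δ*, and the pooled
  variances so it can be frozen on training subjects and applied to
  held-out ones. This matters: harmonizing the whole sample equalizes
  batch means *exactly*, which makes the train-fold and test-fold batch
  deviations anti-correlated — a cross-validated batch classifier then
  lands systematically *below* chance, and any outcome entangled with
  batch inherits the artifact. `evaluate_biomarker(..., combat = list(...))`
  therefore refits ComBat inside every training fold and applies it
  frozen to the held-out fold. The outcome label must never be passed as
  an apply-time covariate (it would leak into the adjusted features);
  fold-safe harmonization uses age and sex only.
* **Group preservation.** With `preserve_group = TRUE` the group code
  joins the design, so the batch terms are estimated net of the group
  contrast. When group and batch are confounded (all cases on one
  scanner), the protected contrast is *re-estimated* from the few
  within-batch controls: with a purely mean-shift generator and a fully
  confounded design, withholding the group label removes most of the
  planted signal, and preserving it replaces the observed contrast with a
  noisy coefficient (visible on single features such as eTIV, which have
  no empirical-Bayes pooling across features). The harmonization
  properties are therefore tested with cases spread across batches, where
  site removal and group preservation can be assessed without the
  confound; the confounded default remains available and behaves as the
  statistics predict.

Harmonization is applied to the raw measures (area, thickness, myelin,
subcortical volumes, eTIV); derived biomarkers are computed from the
harmonized inputs and never re-harmonized. eTIV-normalization (volumes as
% of eTIV) happens after harmonization.

## Feature construction

* Pairwise inter-regional differences use a fixed row-major
  upper-triangle order — (1,2), (1,3), …, (1,n), (2,3), … — for
  deterministic serialization; at 360 parcels this is 64,620 features.
* The PCA reduction of wide feature sets retains the smallest number of
  components reaching 95% cumulative variance (configurable), capped at
  n_train − 1, and is always fitted on training folds only.
* Partial correlations come from the inverse of a shrinkage-regularized
  correlation matrix, `R_λ = (1−λ)R + λI`, with
  `partial_r = −Ω_ij/√(Ω_ii Ω_jj)`. With p = 360 parcels and modest scan
  lengths the sample correlation is ill-conditioned, so `λ = "auto"` uses
  the analytic intensity `Σ Var(r_ij) / Σ r_ij²` (clipped to
  [0.01, 1]). Correctness is pinned by the p = 2 equivalence with Pearson
  r, the chain-graph conditional-independence oracle, and the λ = 1
  limit, rather than by reproducing any particular published recipe.
* Degree centrality is Σ|partial r| per region. Gradients are the first
  two principal components over the rows of the *Pearson* connectome
  (each region's connectivity profile is one observation), without
  thresholding — thresholds would add an unstated free parameter. Because
  per-subject PCA axes are arbitrary up to rotation and sign, subject
  gradients are aligned to a control-group reference by orthogonal
  Procrustes over the two components; alignment identity and sign-flip
  invariance are tested.

## The validation protocol

* **Single-step mode** (default): stratified 5-fold cross-validation over
  all subjects. Within each training fold the majority class is randomly
  down-sampled to the minority count; held-out folds keep their natural
  imbalance. The learner is a 500-tree random forest (`ranger`); the
  features-per-tree parameter is either √p or tuned by inner 3-fold
  cross-validation over a grid (3–10 for the behavioral table). The
  protocol, not the learner, is the tested artifact.
* **Vote shares.** Each subject's held-out score is the fraction of trees
  voting "case" — a per-subject classifiability index that can be
  correlated with covariates such as the number of types.
* **AUC** is the Mann–Whitney rank statistic with half-credit ties
  (verified against exhaustive pair counting and pROC); sensitivity and
  specificity use a 0.5 vote threshold, with exact 0.5 counted as a
  control vote.
* **Permutation nulls** re-run the entire protocol (folds, down-sampling,
  tuning, reduction, fold-safe harmonization if any) on shuffled labels;
  the empirical p uses the add-one tail correction
  `(1 + #{null ≥ observed}) / (n_perm + 1)`.
* **Staged mode** reproduces the discovery / demonstration /
  generalization design: cases with 3+ types fill discovery and
  demonstration (25 each, seeded; proportional fallback with a recorded
  trace when fewer than 50 are eligible), remaining cases generalize;
  large-batch controls are halved between discovery and demonstration,
  local controls serve discovery only. The tuning parameter is selected
  within discovery and frozen — the open question of per-fold re-tuning
  versus freezing is resolved in favor of freezing, matching the staged
  design's logic.

## Statistics

Pooled-variance (Student) t-tests per region — chosen over Welch because
the pipeline reports pooled-SD Cohen's d alongside — with
Benjamini–Hochberg FDR across regions. The AUC↔d conversion uses the
equal-variance binormal model, d = √2·Φ⁻¹(AUC). Mahalanobis D uses the
pooled covariance, with the standard unbiased correction of the squared
distance, `D_u² = ((N−p−3)/(N−2))·D² − pN/(n_A n_B)` floored at zero; its
correctness anchor is a simulation showing the corrected null mean is
unbiased where the raw estimate is visibly inflated (p = 35,
n = 128/109). `detectable_d` inverts the noncentral-t power function by
bisection to 1e-6.

## Numerical conventions and degenerate inputs

Cohorts and matrices serialize as TSV with 12-significant-digit floats
(deterministic byte streams; round-trips are lossless well beyond 1e-9
relative). Constant feature columns are dropped with a message before
classification; zero-variance parcels, batches with one subject,
rank-deficient designs, unseen batch levels, asymmetric "symmetric"
matrices, and missing subjects all raise informative errors naming the
offender. All stochastic steps are seeded; identical seeds give
byte-identical cohorts and identical cross-validation results.

## Scales used by the tests

The suite exercises full-size combinatorics (360 parcels → 64,620 pairs)
where cheap, and scaled cohorts elsewhere: calibration of the permutation
null uses 200 subjects × 360 features × 200 permutations; parameter
recovery uses 150 subjects per group; hub-flattening uses 100 per group
with 120 timepoints; the end-to-end analysis scripts use 60 cases / 130
controls over 90 parcels. These sizes were chosen so the whole suite runs
in minutes while every statistical check retains adequate power; all
constructions are size-agnostic.

## Known limitations

* The generator's group signal is purely first- and second-moment
  structure; classifiers that exploit higher-order structure in real data
  are not represented.
* The partial-correlation regularization is a standard analytic shrinkage
  toward the identity, not a reproduction of any specific published
  pipeline's (unspecified) recipe.
* Surface-area features are parcel-level and unweighted; vertex-level
  thickness-weighted aggregation is out of scope, and parcel thickness is
  taken as given (the median-across-vertices convention becomes a
  pass-through at parcel granularity).
* Under full group–batch confounding no harmonization scheme can both
  remove the batch effect and recover the group contrast from mean
  structure alone; the package makes the trade-offs visible rather than
  hiding them.
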