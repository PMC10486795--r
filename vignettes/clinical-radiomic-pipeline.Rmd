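---
title: "Clinical-radiomic modelling of ICC grading and microvascular invasion"
author: "iccradiomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clinical-radiomic modelling of ICC grading and microvascular invasion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iccradiomics)
```

## The problem this package addresses

Intrahepatic cholangiocarcinoma (ICC) is an aggressive primary liver cancer
whose two strongest pathology markers — histologic grading (G3, poorly
differentiated, versus G1-2) and microscopic vascular invasion (MVI) — are
only known after resection. CT radiomics offers a non-invasive preoperative
surrogate: quantitative texture, intensity and shape descriptors of the
tumor (Tumor-VOI) and of a 5 mm rim of peritumoral parenchyma (Margin-VOI)
segmented on the portal venous phase, combined with routine clinical
covariates in a logistic model.

`iccradiomics` implements that analysis end to end as reusable, tested
code: VOI geometry, the 45-index radiomic feature panel, cohort assembly
(missing-data policy, chained imputation, correlation pruning), logistic
model families with subset selection, a random-intercept center model with
its variance partition coefficient (VPC), stratified 50-fold
cross-validation, and paired one-sided permutation tests between nested
model families. Because no patient-level data are deposited with the study
this design follows, the package ships a synthetic phantom and cohort
generator that reproduces the *statistical structure* the analysis assumes;
every pipeline stage is exercised against it.

## VOI geometry

A volume is a 3D array of Hounsfield units with per-axis voxel spacing in
mm (array order `[x, y, z]`, first index fastest). The Margin-VOI is built
by metric dilation: a voxel belongs to the dilated set when its center lies
within the radius (default 5 mm) of some tumor voxel center, with distances
measured in physical mm so anisotropic spacings (e.g. 5 mm slices) behave
correctly. The margin is the dilated set minus the tumor.

Two deliberate strictness choices:

* dilation that would leave the image grid raises an error instead of
  silently truncating the rim;
* the margin is clipped only by the grid, never by an organ mask. A real
  margin may cross the liver boundary into vessels or gallbladder; whether
  the original analysis excluded such voxels is unknown, so this
  implementation keeps them and documents the simplification.

## The 45 radiomic indices

Per VOI the panel contains 7 grey-level descriptors (HUmin, HUmean, HUstd,
HUmax, HUQ1/Q2/Q3), 4 first-order histogram parameters (skewness, kurtosis,
histogram energy and entropy), 3 shape indices (volume in mL, sphericity,
compacity), 6 GLCM, 11 GLRLM, 3 NGLDM and 11 GLZLM features — 45 keys,
namespaced `<Phase>_<VOI>_<Name>` (e.g. `Portal_Margin_GLZLM_ZLNU`).
The family counts quoted in the radiomics literature for this panel
sometimes sum to 46 because GLCM entropy is printed in two logarithm bases;
this package counts that index once (log2) to keep a stable 45-key
contract.

Numerical choices, all covered by tests against independent brute-force
oracles on small VOIs:

* **Discretization.** Default: 64 grey levels over the VOI min-max (scale-
  and shift-invariant); a fixed-bin-size mode over an absolute HU window is
  available. The level of the original analysis' software is not published,
  so the default favors invariance.
* **GLCM/GLRLM.** All 13 unique 3D directions at distance 1, restricted to
  in-mask voxel pairs/runs; feature values are computed per direction and
  averaged (a merged-matrix mode is a flag). Correlation on a zero-variance
  matrix is undefined and reported as `NA` with a warning — the package-wide
  sentinel policy; keys are never dropped, so the modelling contract is
  stable.
* **NGLDM.** 26-connected in-mask neighborhoods; voxels with no in-mask
  neighbor contribute zero difference. Single-level VOIs give Contrast 0
  and leave Coarseness/Busyness degenerate (sentinel).
* **GLZLM.** Zones are 26-connected components of constant level, found by
  iterative minimum-label propagation (exact, matches a flood-fill oracle).
* **Quantiles.** Inclusive linear interpolation (R type 7).
* **Surface area.** The binary mask is mildly smoothed (Gaussian,
  sigma = 0.9 x min spacing) and triangulated at the 0.5 level by marching
  tetrahedra with linear edge interpolation. A mesh on the *raw* binary
  staircase would not converge to the true area under refinement (it keeps
  the staircase inflation), whereas the smoothed mesh brings a digital
  sphere's sphericity from 1.023 (radius 8 voxels) to 0.997 (radius 20).
  The cost is that sharp corners are rounded: small cubes measure
  *higher*-than-true sphericity with the mesh, which is why the cube closed
  form is checked with the exact voxel-face-count estimator instead.
  Compacity is defined as A^{3/2}/V.

## Cohort assembly

* **Missing-data policy.** Rows missing an outcome or any radiomic feature
  are excluded; covariates missing in >= 15% of rows are dropped from
  modelling; covariates below the threshold go to imputation.
* **Imputation.** Chained equations: each incomplete column is iteratively
  regressed on the others and missing cells are replaced by draws from the
  fitted predictive distribution (normal linear for numeric, logistic for
  binary columns). Observed cells are never altered; one completed dataset
  per seed (the analysis this mirrors reports one analysis, not pooled
  estimates); multiple imputations are obtained by varying the seed.
* **Pruning.** Pearson correlation on raw feature values, absolute value
  compared with 0.85; the Tumor-VOI and Margin-VOI blocks are pruned
  independently. When a pair offends, the member with the larger mean
  absolute correlation to the remaining features is dropped (deterministic
  column-order tie-break). The kept set provably satisfies
  max |r| <= 0.85 — asserted on every run. Spearman is a plausible
  alternative the source analysis may have used; Pearson is the documented
  choice here.
* **Standardization.** Continuous predictors are z-scored with *training*
  statistics, so coefficients and ORs are per SD — consistent with final
  published ORs for continuous radiomic features lying near 1.

## Models

`fit_logistic()` fits maximum-likelihood logistic regression (Wald ORs,
bounds, p-values) or lasso/ridge via penalized deviance with the penalty
chosen by internal cross-validation under a fixed seed. Complete separation
is detected and flagged with a suggestion to use a penalized family, never
silently returned.

`backward_select()` (also forward/stepwise) eliminates whole terms by AIC
using fast IRLS refits; an alpha-threshold mode is available. AIC was
chosen over a strict p < 0.05 drop rule because final models in this
setting typically retain terms with p around 0.09-0.11, which a 0.05 rule
could not produce. Clinical candidates can first pass univariate screening
(chi-square/Fisher for categorical — Fisher when an expected cell count is
below 5 — and t/Mann-Whitney for continuous, with normality mechanized as
|skewness| < 1 and |excess kurtosis| < 2 in place of graphical assessment)
at p < 0.1, plus an a-priori list.

`fit_mem()` adds a per-center random intercept via `lme4::glmer` and
reports the center effect as the latent-threshold VPC,

$$\mathrm{VPC} = \frac{\sigma^2_u}{\sigma^2_u + \pi^2/3},$$

the standard formulation for logistic mixed models (residual variance of
the latent logistic scale is \(\pi^2/3\)). Closed-form checks: VPC(0) = 0 and
VPC(\(\pi^2/3\)) = 0.5 exactly; simulation recovery at generative VPC 0.25
and 0.5 is tested at 30 centers x 200 patients. At that size the VPC
estimate from a single dataset has a standard error around 0.05, so
recovery is asserted within +-0.08.

## Validation

`stratified_cv()` runs stratified k-fold cross-validation with k = 50 by
default. With n around 244 this means ~5-patient held-out folds: per-fold
metrics are extremely variable (SDs of 0.2-0.4 are expected, matching the
large reported SDs in this literature), and folds whose held-out part
contains a single class have an undefined panel — they are excluded from
the mean with a reported count. The entire pipeline (standardization,
pruning, screening, selection) is re-run inside each training split by
default, so the held-out fold never informs selection; whether the original
analysis refit selection per fold is not stated, and a
`refit_selection = FALSE` mode (select once, refit coefficients per fold)
is provided. Threshold metrics use predicted probability 0.5 (no threshold
is published).

`permutation_compare()` performs the paired one-sided test between two
models cross-validated on identical folds: per-fold metric differences are
sign-flipped (default 10,000 draws) and
\(p = (1 + \#\{\bar d^* \ge \bar d\}) / (1 + n_{perm})\).
A sign-flip over paired fold metrics was chosen because the comparison is
between "average performance" of two models evaluated on the same cohort;
label permutation would test a different null. Calibration is verified by
simulation: under an exchangeable null the rejection rate at alpha = 0.05
stays in the nominal range, and a uniformly shifted pair attains the
minimum attainable p-value \(1/(1+n_{perm})\).

## The synthetic generators

`make_phantom()` emulates a portal-phase CT sub-volume: background
parenchyma plus a spatially correlated texture field (white noise smoothed
with a Gaussian kernel of width `texture_corr_len_mm`, rescaled to unit SD,
scaled by `heterogeneity` in HU) plus independent voxel noise, with an
ellipsoidal lesion shifted to `tumor_hu`. Defaults (70/90 HU background/
lesion, 8 HU noise, 2 mm correlation length, ~1 cm lesion, 1 mm voxels) are
in the range of portal-phase liver CT. In the noise-free limit the phantom
is exactly two-valued; with heterogeneity linked to a latent class, texture
features of tumor and margin separate between classes, increasingly so for
larger heterogeneity gaps (rank-test property).

`make_cohort()` draws a multicenter cohort table: clinical covariates from
documented marginals chosen to resemble a surgical ICC population (median
age ~67, ~51% female, HBV 7.8%, HCV 11.1%, cirrhosis 10.7%, log-normal
diameter with median 50 mm, tumor pattern 1/2/3 at 62/25/13%, log-normal
CA 19-9 with median 29 U/mL, chemotherapy 10.7%, major hepatectomy 52.5%);
feature columns from an AR(1)-correlated multivariate normal (or attached
from phantom extraction); per-center random intercepts with SD `center_sd`
(default 1.0, i.e. VPC around 0.23, the magnitude reported for center
effects in multicenter radiomics); and outcomes `G3`/`MVI` from the
logistic model with intercepts calibrated so expected prevalence hits the
targets (defaults 0.336 and 0.57). Missingness is MCAR only (default 12.3%
of CA 19-9), because the imputation *rule* is what the pipeline tests —
informative missingness is out of scope. Two published marginals (84.4%
solitary tumors vs 61.9% pattern type 1) are mutually inconsistent as a
joint distribution; the generator draws the two columns independently from
their own marginals and claims marginal realism only.

What passing tests on these generators do show: the geometry, features,
selection rules, model fits and validation machinery compute what they
claim, with correctly calibrated error rates. What they do not show:
performance numbers on real multicenter CT (scanner effects, segmentation
variability, anatomy, informative missingness are not simulated), so
cross-validated AUCs on synthetic cohorts characterize the *pattern*
(clinical < +Tumor <= +Tumor+Margin when both blocks carry signal), not the
published point estimates.

## Problem sizes used by the shipped checks

The test suite and `scripts/acceptance.R` size their simulations for a
laptop-class single core: texture oracles on 200 random VOIs up to 6^3;
OR-2 recovery at n = 5000; backward-selection retention over 100 replicates
at n = 1000 with 10 noise features; VPC recovery at 30 centers x 200
patients; permutation calibration over 200 null replicates; and the
nested-model pattern over 244-patient cohorts with 50-fold CV (20
replicates in the test suite, 12 in the acceptance script). These sizes are
the package's documented defaults for its own verification.

## Known limitations

* No liver-boundary exclusion for the margin; no registration between
  phases (an arterial volume, if supplied, is assumed pre-aligned).
* Mesh surface area is biased high for small, sharp-cornered shapes (see
  above); voxel-face area is available where exactness matters.
* LifeX-byte-exact parity is a non-goal: discretization bounds and the
  direction-aggregation mode of the original software are unpublished, so
  both options are exposed instead.
* CART/Random Forest are deliberately absent (abandoned in the source
  analysis for instability at this n/p); survival endpoints and external
  validation are out of scope.
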