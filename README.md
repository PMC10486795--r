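# iccradiomics

Clinical–radiomic modelling of tumor grading and microvascular invasion in
intrahepatic cholangiocarcinoma (ICC), as an R package.

ICC is an aggressive primary liver cancer whose strongest prognostic
markers — histologic grading (G3 vs G1-2) and microscopic vascular invasion
(MVI) — are determined only at pathology, after surgery. A preoperative
surrogate can be built from portal-phase CT: radiomic features of the
segmented tumor (Tumor-VOI) and of a 5 mm peritumoral rim (Margin-VOI),
combined with routine clinical covariates in a logistic model. This package
implements that analysis end to end, for methodologists and imaging groups
who want the pipeline as tested, reusable code rather than a one-off
script:

* **VOI geometry** — metric (anisotropy-aware) mask dilation in physical
  mm; the Margin-VOI is `dilate(tumor, 5 mm) \ tumor`; NIfTI I/O.
* **Features** — the 45 retained radiomic indices per VOI: HU descriptors,
  first-order histogram parameters, shape (volume, sphericity, compacity),
  GLCM, GLRLM, NGLDM and GLZLM texture families, computed in 3D over the
  13 unique directions / 26-neighborhood and verified against
  brute-force enumeration oracles.
* **Cohort assembly** — missing-data policy (drop rows missing outcomes or
  features; exclude covariates ≥ 15% missing), chained-equation
  imputation, and pairwise-correlation pruning (|r| > 0.85, per VOI block).
* **Models** — logistic regression with backward/forward/stepwise AIC
  selection (`backward_select()`), lasso/ridge (`fit_logistic()`), and a
  random-intercept center model (`fit_mem()`) with its variance partition
  coefficient, VPC = σ²ᵤ / (σ²ᵤ + π²/3).
* **Validation** — stratified k = 50 cross-validation with the whole
  selection pipeline re-run inside each training fold, a six-metric panel
  (ROC AUC, PR AUC, sensitivity, specificity, accuracy, precision), and
  paired one-sided sign-flip permutation tests between nested model
  families, p = (1 + #{d̄* ≥ d̄}) / (1 + n_perm).
* **Synthetic generators** — `make_phantom()` (lesion-bearing CT-like
  volumes with controllable texture heterogeneity) and `make_cohort()`
  (multicenter cohorts with clinical effects, feature effects and
  per-center random intercepts), so every stage is testable without
  patient data. The patient cohort behind the design is not publicly
  deposited; all shipped checks run on these generators plus published
  marginal counts.

## Worked example

Simulate a 244-patient, 6-center cohort in which one Tumor-VOI and one
Margin-VOI feature carry real signal for G3, then fit and validate the
combined clinical–radiomic model:

```r
library(iccradiomics)

cfg <- cohort_config(
  n_patients = 244, n_centers = 6, center_sd = 0.5,
  beta_features = list(G3 = c(Portal_Tumor_F1 = 0.7, Portal_Margin_F1 = 0.7)),
  missing_rate = 0, seed = 42)
tab <- make_cohort(cfg)

rec <- model_recipe("G3",
  tumor_features  = paste0("Portal_Tumor_F", 1:8),
  margin_features = paste0("Portal_Margin_F", 1:8))
fit <- fit_pipeline(rec, tab)
print(fit)
#> <icc_pipeline> outcome G3, selection backward
#>   candidates: 17 (clinical 1, tumor 8, margin 8 after pruning)
#> <icc_logit> ml logistic model of G3 (n = 244)
#>              term coefficient    OR lower upper  p_value
#>       (Intercept)      -0.705 0.494 0.365 0.669 4.84e-06
#>   Portal_Tumor_F1       0.663 1.940 1.410 2.670 4.93e-05
#>   Portal_Tumor_F7       0.251 1.290 0.957 1.730 9.55e-02
#>  Portal_Margin_F1       0.626 1.870 1.350 2.600 1.97e-04
#>  Portal_Margin_F5       0.327 1.390 1.030 1.860 2.96e-02
```

Backward selection recovered both planted features (per-SD ORs ≈ 1.9, true
value e^0.7 ≈ 2.0) plus two weak noise terms — the expected behavior of
AIC elimination at this sample size. Cross-validate the clinical-only and
combined models on identical folds and compare them:

```r
cv_clin <- stratified_cv(model_recipe("G3"), tab, k = 50, seed = 7)
cv_full <- stratified_cv(rec, tab, k = 50, seed = 7)
print(cv_full)
#> <cv_result> G3, stratified 50-fold CV (seed 7), selection refit per fold
#>       metric  mean    sd n_excluded
#>      roc_auc 0.708 0.305          0
#>       pr_auc 0.742 0.255          0
#>  sensitivity 0.400 0.404          0
#>  specificity 0.827 0.228          0
#>     accuracy 0.669 0.209          0
#>    precision 0.588 0.399         14

permutation_compare(cv_clin, cv_full, n_perm = 10000, seed = 1)
#> <perm_result> paired sign-flip test, 10000 permutations, H1: b > a (one-sided)
#>       metric mean_diff p_one_sided n_pairs
#>      roc_auc    0.2283   9.999e-05      50
#>       pr_auc    0.3825   9.999e-05      50
#>  sensitivity    0.4000   9.999e-05      50
#>  specificity   -0.1733   1.000e+00      50
#>     accuracy    0.0310   1.723e-01      50
#>    precision        NA          NA       0
```

The radiomic block raises cross-validated AUC by ≈ 0.23 (one-sided p =
1/(1+n_perm), the smallest attainable value). The large per-fold SDs are a
direct consequence of k = 50 on 244 patients (≈ 5-patient held-out folds);
folds where a metric is undefined are excluded and counted
(`n_excluded`; precision is undefined in every fold of a model that never
crosses the 0.5 threshold, hence `n_pairs = 0` in its comparison row).
Quantify the center effect on the selected terms:

```r
mem <- fit_mem(G3 ~ major_hepatectomy + Portal_Tumor_F1, tab)
#> sigma^2_u = 0.139, VPC = 4.1%
```

i.e. ≈ 4% of latent outcome variance sits between centers for this
simulated cohort (generative center SD 0.5).

For image-level work, `make_phantom()` → `make_margin()` → `extract_all()`
produces the 90 namespaced feature values (45 per VOI) from a synthetic
lesion volume; `read_volume()`/`write_volume()` round-trip NIfTI.

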