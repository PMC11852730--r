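---
title: "Methods: an MRI radiomics pipeline for parotid gland tumors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: an MRI radiomics pipeline for parotid gland tumors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Warthin's tumor, a common benign parotid gland neoplasm, mimics malignant
parotid tumors on multiparametric MRI: both can be heterogeneous, show low
apparent diffusion coefficient (ADC) values, and enhance similarly. This
package implements a complete 3D radiomics pipeline for that
discrimination task: paired T2-weighted and ADC volumes with a shared
lesion segmentation go through preprocessing, a filter bank, large-scale
texture feature extraction, a four-stage feature-reduction cascade, a
linear Radiomic Score, and ROC-based diagnostic reporting.

Because no patient images ship with the package, a synthetic cohort
generator (`generate_cohort()`) provides inputs with the statistical
structure the analysis assumes, so every stage is exercised end to end by
tests and by the numbered drivers under `analysis/`.

## Preprocessing (`preprocess_config()`)

Fixed stage order, applied per sequence:

1. **Bias-field correction** (`bias_field_correct()`, T2 only by default).
   A low-degree (default cubic) polynomial is fit to log-intensity over
   the mask support and divided out, preserving the in-mask mean exactly.
   This targets smooth multiplicative coil/field inhomogeneity with a
   deliberately simple, testable model (the planted-field test verifies
   recovery to < 2% RMS); iterative B-spline deconvolution correctors
   solve the same problem with machinery that is not this package's
   concern. ADC maps are computed parameter maps, so correcting them is
   physically dubious; `bias_on = "both"` restores it.
   The fitted log-field is clamped to its in-mask range before
   exponentiation — polynomial extrapolation far from the lesion would
   otherwise dominate the whole-image normalization statistics.
2. **Z-score normalization** (`normalize_intensity()`), whole-image mean
   and population SD, scaled by `normalize_scale = 100`. A plain z-score
   combined with the fixed bin width of 25 would collapse the ROI into a
   single gray level; scale 100 yields ~24 bins over ±3 SD, the standard
   configuration of widely used extraction platforms.
3. **Outlier exclusion** (`remove_outlier_voxels()`): voxels deviating
   more than 3 SD from the ROI mean are removed *from the mask* (never
   clamped). ROI-scoped statistics are used, since every downstream
   feature is ROI-scoped.
4. **Isotropic resampling** (`resample_isotropic()`) to 1×1×1 mm: Keys
   cubic-convolution interpolation (a = −0.5, interpolating, no
   prefilter) for images; linear interpolation + 0.5 threshold for masks,
   which gives smoother boundaries than nearest-neighbor when upsampling
   3 mm slices. Output dimensions are `round(dim · spacing / target)`
   with first voxel centres aligned.
5. **Discretization** (`discretize_roi()`): fixed bin width W = 25,
   `level = floor((x − min_ROI)/W) + 1`, anchored at the ROI minimum so
   levels are invariant to adding multiples of W.

## Filter bank (`apply_filter_bank()`)

Eleven images per sequence: the original, 8 sub-bands of a single-level
*undecimated* 3D wavelet decomposition (Coiflet-1 by default; undecimated
so sub-band voxels stay aligned with the mask; sub-band letters name the
x, y, z filters in that order), and two scale-normalized
Laplacian-of-Gaussian responses at σ = 3 mm (fine) and 5 mm (coarse).
Each filtered image is discretized independently with the same W. Both
operators are linear and kill constants — properties the tests assert
directly, along with tap-level agreement with naive separable convolution.

## Feature set (`extract_all()`)

Per sequence: 14 shape features from the shared mask geometry, plus 93
intensity/texture features (18 first-order, 24 GLCM, 16 GLRLM, 16 GLSZM,
14 GLDM, 5 NGTDM) on the original and on each of the 10 filtered images —
1037 per sequence, 2074 per lesion. Conventions:

- Matrix families use the 13 unique direction offsets of the
  26-neighborhood at distance 1; GLCM matrices are symmetrized; features
  are averaged per direction (not matrix-merged).
- Degenerate inputs are defined, not `NaN`: single-gray-level ROIs give
  Correlation = MCC = 1 and zero contrast; constant ROIs give
  skewness/kurtosis 0; NGTDM denominators carry an ε = 10⁻⁶ guard
  (Coarseness capped at 10⁶).
- First-order Entropy/Uniformity use the discretized levels; kurtosis is
  *not* excess-corrected (a normal sample gives ≈ 3).
- Every matrix feature is checked against an exhaustive brute-force
  enumeration oracle (plain-loop pair/run/zone/neighborhood counting) on
  100 random 6³ grids at 10⁻⁹ tolerance.

**Surface mesh.** Shape area/volume come from an iso-surface of the mask
at level 0.5, extracted by body-centered marching tetrahedra: each cell
splits into 24 tetrahedra around its centre, with face/cell centres
carrying corner-mean values. The symmetric decomposition avoids the
diagonal bias of the classic 6-tetrahedra split, and the averaged centre
values anti-alias binary data. A light Gaussian pre-smoothing of the
binary mask (σ = 0.6 voxel) further suppresses staircase faceting: a
digitized 10 mm-radius ball then meshes at sphericity 0.973 and −0.7%
volume error. The known cost is edge rounding on shapes with sharp
corners: a 10 mm cube meshes ~5–8% below its closed-form surface area
(sphericity 0.87 vs the ideal 0.806) — an inherent property of voxel-mesh
surface estimation, acceptable for anatomical (smooth) lesions.

## Feature-reduction cascade (`run_selection_cascade()`)

1. **ICC stability gate**: ICC(A,1) — two-way mixed-effects, absolute
   agreement, single measures, the conventional intra-observer variant —
   between original and repeat segmentations of the 30-lesion stability
   subset; retain ICC > 0.85 (strict). Zero-variance features report
   ICC 0 with a warning.
2. **Univariate screen**: two-sided Mann–Whitney U per feature (exact
   enumeration when both groups ≤ 8 without ties, otherwise the normal
   approximation with tie correction), Benjamini–Hochberg adjustment
   jointly across both sequences' features (one correction is described;
   `bh_scope = "per_sequence"` is available), retain adjusted p < 0.05.
   `alpha = 1` is a documented degenerate switch that disables the screen.
3. **Spearman redundancy pruning**: pairs with |ρ| > 0.9 processed in
   decreasing |ρ| (then lexicographic) order; the member with the larger
   univariate p is eliminated, ties to the lexicographically later name —
   fully deterministic.
4. **LASSO**: features standardized with training means/SDs (stored in
   the model, so test rows are never standardized with their own
   statistics), L1-penalized logistic regression (WT encoded 1, scores
   higher for Warthin-like lesions) with λ minimizing the 10-fold
   cross-validated binomial deviance over seeded class-stratified folds
   ("minimum criterion"; λ-1SE available via `lambda_rule`).

The Radiomic Score is `I + Σ C_y·V_y` over the surviving standardized
features. When a null cohort leaves nothing for the LASSO, the pipeline
completes with an intercept-only constant score (AUC 0.5, degenerate CI)
rather than failing; the standalone `fit_lasso_score()` still errors so
interactive users see the λ-path problem.

## Evaluation

- `stratified_split()`: per class, ceil(n/4) lesions to the test set — the
  "one-third of the training set" allocation that maps 66 + 40 lesions to
  79 training / 27 testing with the expected class breakdown. Splits are
  by lesion (multi-lesion patients carry same-class lesions).
- `roc_auc_ci()`: Mann–Whitney AUC (ties ½) oriented WT-high, DeLong
  variance for the 95% CI and the p-value against 0.5; cross-checked
  against pROC in the tests.
- `optimal_cutoff()`: Youden's J over midpoints of sorted unique scores
  (the default criterion of the common clinical ROC software), malignant
  called *below* the threshold, ties resolved toward the score median.
- `diagnostic_metrics()`: Se/Sp (malignant positive) with Clopper–Pearson
  exact CIs; ±LR with log-method CIs, continuity-corrected (and one-sided)
  when a cell is empty.

## The synthetic cohort

`generate_cohort()` emulates the study conditions: 106 lesions (66 WT,
40 MT), ~20% of patients carrying a second same-class lesion, ROIs of
32×32×16 voxels at 0.7×0.7×3 mm, ellipsoidal masks with in-plane
diameters U(12, 20) mm (the ROI is 22.4 mm across) and axial diameters
U(12, 40) mm — every lesion over the 1 cm inclusion bound; 30 lesions
(15 per class) carry a boundary-jittered re-segmentation (default jitter
one in-plane voxel, giving Dice ≈ 0.93–0.98 and an ICC spread that
straddles the 0.85 gate nontrivially).

Lesion texture is a class-conditional Gaussian random field: white noise
smoothed to a class-specific correlation length, scaled to a
class-specific SD, on a class-specific mean, with per-lesion lognormal
parameter jitter (CV 0.15) for biological variability. Three effects are
planted (all scaled by `effect_profile(strength)`, null at 0):

| effect | WT | MT (strength 1) | primarily drives |
|---|---|---|---|
| mean level (raw a.u.) | 320 | 355 | first-order mean/RMS |
| correlation length (mm) | 2.5 | 4.0 | GLSZM zone structure |
| texture variance ratio | 1 | 1.5 | GLRLM level emphasis, spread |

Background tissue sits at 250 ± 40 a.u.; additive noise SD 15; a planted
±10% smooth multiplicative bias field exercises the corrector. The
ADC-like volume is anti-correlated with the noise-free T2 signal (high
"cellularity" → low ADC) on a plausible physical scale, clamped to
400–2500 ×10⁻⁶ mm²/s. These values were fixed once as plausible
study-like conditions and are not tuned.

What the generator does *not* emulate: MRI physics (no k-space,
reconstruction, or b-value diffusion model), scanner-to-scanner
variation, irregular lesion shapes, or infiltrative margins. Passing
tests therefore demonstrate that the pipeline machinery is correct and
that the cascade recovers known planted structure — not that the score
would reach any particular performance on real patients.

"Recovery" of a planted family is measured at the univariate-screen
stage (at least one BH-significant feature in the family), because the
redundancy pruning deliberately collapses correlated clusters to single
representatives that may come from another family.

## Problem sizes and numerical choices

- The planted-effect acceptance run uses the full default cohort
  (106 lesions, all filters, 2074 features). Null-calibration replicates
  (20) use reduced cohorts — 20 + 20 lesions, 16×16×8 ROIs at 1×1×3 mm,
  original-image features only — since statistical calibration is
  scale-free; chosen so the whole suite runs comfortably on a laptop.
- Oracle equivalence uses 6³ level grids, large enough to exercise every
  direction/connectivity case while keeping exhaustive enumeration cheap.
- Tolerances: 10⁻⁹ for oracle equivalence (pure arithmetic), 10⁻⁶ for
  linear-operator identities, statistical bands elsewhere (e.g. null CI
  coverage ≥ 0.85 of nominal 0.95 over 20 replicates).
- All randomness flows from explicit seeds (cohort, split,
  cross-validation folds derive distinct sub-seeds from one global seed);
  reruns are bit-identical.

## Known limitations

- The simplified polynomial bias corrector handles smooth fields only;
  severe or discontinuous inhomogeneity is out of scope.
- Mesh-based surface area carries the voxel-mesh biases described above.
- The wavelet family of the reference platforms is configurable but only
  Coiflet-1 and Haar taps ship built-in.
- With 2074 candidate features and 79 training lesions, the LASSO
  training AUC is optimistically biased (the held-out test AUC is the
  honest number) — the cascade reduces but does not eliminate
  overfitting, which is precisely why the held-out split exists.
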