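---
title: "Methods: a tile-based H&E texture signature for chemoradiotherapy response"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a tile-based H&E texture signature for chemoradiotherapy response}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the model

Locally advanced rectal cancer is usually treated with neoadjuvant
chemoradiotherapy (nCRT) before surgery, but a substantial fraction of
patients respond poorly (tumour regression grade 2/3, "PR") and gain little
from the delay. `pathsig` implements a digital-pathology pipeline that
predicts PR status from the pre-treatment biopsy H&E slide alone:

1. **Tiling.** The pathologist-annotated tumour region is cropped to its
   minimum bounding rectangle, block-mean downsampled by a factor of 2
   (×400 → ×200 magnification) and cut into non-overlapping 512 × 512 pixel
   tiles; tiles over dense tumour tissue are selected (either by replaying
   an explicit list, as in manual curation, or by a tissue-fraction rule).
2. **Texture features.** Each tile yields a 104-dimensional descriptor: the
   13 classical Haralick statistics of symmetric, normalized gray-level
   co-occurrence matrices at distances {1, 2} pixels and angles
   {0°, 45°, 90°, 135°}, computed on Rec. 601 luminance quantized to G = 64
   levels over the fixed range [0, 255].
3. **Selection and tile classifier.** Features are z-scored with
   primary-cohort parameters, screened by L1-penalized (LASSO) logistic
   regression with 10-fold cross-validation, and the retained features feed
   an RBF-kernel SVM whose Platt-calibrated output is the tile-level
   probability of poor response.
4. **Patient aggregation and pathology score.** A patient's characteristic
   is the arithmetic mean *m* of their tile probabilities; a univariable
   logistic fit of outcome on *m* defines the pathology score
   *s* = expit(β₀ + β₁ m). Because *s* is strictly monotone in *m*, both
   carry the same ranking (identical AUC).
5. **Evaluation.** Cohorts are split 80:20 (primary:validation, stratified
   by outcome); discrimination is summarised by rank-based AUC with
   stratified percentile-bootstrap (or DeLong) intervals and by threshold
   metrics at Youden's J chosen on the primary cohort; calibration by
   decile calibration curves and the Hosmer–Lemeshow (H-L) chi-square;
   clinical utility by decision-curve net benefit; and cohort composition
   by Table-1-style summaries with univariable association tests.

Tile labels are inherited from the patient outcome — there is no tile-level
ground truth. This deliberately injects label noise (not every tumour tile
carries the response-associated morphology), which the patient-level mean
absorbs.

## The synthetic cohort generator

The slides behind the original cohort are not public, so the package ships
a first-class generator whose output exercises every stage:

* **Tiles.** Nuclei are placed by a homogeneous Poisson process (density
  `nucleus_density` per pixel²) and drawn as anti-aliased filled ellipses
  with random orientation and aspect ratio in [1, 1.6], over an eosin-like
  background; overlap is permitted and composited through a transmittance
  field, since only second-order statistics matter downstream. One Gaussian
  speckle field (SD `speckle_sd` gray levels) is shared by the three
  channels, i.e. channel-correlated sensor noise; features are computed on
  luminance, so per-channel noise would add cost without changing the
  texture statistics. The palette is fixed (background ≈ (230, 200, 220),
  nuclei ≈ (90, 60, 130)); intensity parameters rescale it multiplicatively.
* **Classes.** `class_params_for_effect(effect_size)` maps a dimensionless
  separation to two parameter sets: the poor-response class gets denser
  (+45 %·effect), slightly larger (+10 %·effect), darker (−15 %·effect)
  nuclei and stronger speckle (+40 %·effect). At `effect_size = 0` the two
  classes are a single distribution; `effect_size = 1` is the package's
  strong-separation reference condition.
* **Cohorts.** The default configuration is 60 patients, poor-response
  prevalence 59/120 (the published primary-cohort prevalence), and 10–20
  tiles per patient — about 900 tiles, a scale chosen so that a full run
  (generation, features, selection, SVM, evaluation) completes in well
  under a minute on one CPU while keeping ≈ 150–300 tiles per class in the
  primary set, enough for stable selection. Clinical covariates (age,
  gender, T/N stage, CEA) are sampled independently per column from the
  published class-conditional margins (`reference_table1()`); only margins
  are published, so no covariate correlation is emulated.
* **Reproducibility.** One root seed fans out to per-stage and per-tile
  substreams by counter (`derive_seed()`), so cohorts are bit-identical
  across runs and tiles can be regenerated individually; cohort objects
  carry tile seeds, not pixels, keeping memory flat.

What passing tests on this generator do **not** show: robustness to stain
variation, scanner artifacts, tissue-fold/blur quality problems, realistic
nuclear pleomorphism or gland architecture, or covariate–outcome
confounding. The generator makes the two classes differ exactly and only
in second-order texture; real slides differ in many more (and fewer
controllable) ways.

## Numerical and design choices

* **104 features.** The descriptor's published size is reproduced exactly
  by 13 Haralick statistics × 2 distances × 4 angles; this is the only
  composition of the standard statistic set that gives 104, and it fixes
  the canonical ordering `{stat}_d{distance}_a{angle}`.
* **Haralick conventions.** Natural logarithms; 0·ln 0 = 0; sum variance is
  centred on the sum average (the modern convention; some older texts
  centre it on sum entropy); for a zero-variance (degenerate) matrix,
  correlation := 1 and IMC1 := IMC2 := 0, the constant-image limit.
* **Quantization** is uniform over the fixed global range [0, 255]
  (bin = ⌊v·G/256⌋), never per-image min–max, so per-tile brightness cannot
  leak into texture.
* **Downsampling** is an exact block mean (alias-free, deterministic, full
  precision); partial border tiles are dropped, never padded, keeping the
  512 × 512 contract exact. The grid is anchored at the crop origin; no
  anchor search is performed.
* **LASSO.** Penalty grid from glmnet; chosen penalty minimises mean CV
  binomial deviance (the sparser one-standard-error rule is available via
  `rule = "1se"`). CV folds are grouped by patient — all tiles of a patient
  share a fold — because tiles inherit the patient label and ungrouped
  folds would leak identity. If nothing is selected (expected under a null
  cohort), the tile classifier degenerates to the constant probability 0.5
  and the signature to the prevalence, keeping the pipeline total.
* **SVM.** Radial kernel; grid C ∈ 2^{−3..7}, γ ∈ 2^{−9..1} in log₂ steps
  of 2; stratified 5-fold CV maximising out-of-fold AUC; probabilities are
  Platt-scaled by libsvm's internal cross-validated sigmoid fit.
* **Split.** Primary size is ⌊n·ratio⌋ (151 patients at 80 % → 120/31,
  matching the published cohort sizes); stratified allocation floors the
  per-class counts and distributes the remainder by largest fractional
  part.
* **Univariable tests.** Pearson chi-square with the conventional
  continuity correction on 2 × 2 tables — this reproduces the published
  gender (.401) and CEA (.134) p-values, which uncorrected chi-square does
  not — and Fisher's exact test when any expected count is below 5
  (configurable; the published T-staging value matches uncorrected
  chi-square despite a sparse row, so `fisher_when_sparse = FALSE` replays
  it). Continuous variables default to Mann–Whitney, consistent with
  median (IQR) reporting; Welch's t is available.
* **H-L test.** g = 10 equal-frequency bins (reduced to ⌊n/2⌋ for small
  cohorts), H = Σ (O−E)²/(E(1−E/n_g)), χ² with g − 2 df; degenerate bins
  are merged with a warning.
* **Bootstrap.** Stratified percentile bootstrap (positives and negatives
  resampled separately, so every replicate keeps both classes), B = 2000 by
  default (500 inside the pipeline report for speed), fixed seed; DeLong
  intervals for AUC via pROC as an alternative.
* **Youden threshold.** Maximises sensitivity + specificity − 1 over
  observed primary-cohort scores, ties to the lowest threshold; reused
  unchanged on validation.
* **Separation fallback.** Small-cohort signature fits can separate
  perfectly; the fit then falls back to a ridge penalty of 10⁻⁴ with a
  warning rather than diverging.

## Open questions resolved as package choices

Where the study's write-up is silent, the package fixes a choice and
documents it here: the LASSO is logistic (not linear), folds are
patient-grouped, partial tiles are dropped, the split is stratified, the
pixel scale of the synthetic tiles is arbitrary (no µm calibration is
claimed), and the identity of the selected features is not asserted —
only the pipeline's behaviour, since the published list of 17 selected
features is not available for comparison.

## Problem sizes used by the test suite

The simulation suites run at deliberately chosen scales: the GLCM oracle on
100 random 16 × 16 images; signature parameter recovery at n = 2000; H-L
type-I error over 500 calibrated datasets of n = 1000; LASSO planted-signal
recovery over 20 seeds of 500 × 104; and the end-to-end recovery study at
the reference condition (60 patients, one strong-effect run plus ten
null-effect seeds, whose validation folds hold 12 patients each — single
null AUCs are therefore noisy, and the suite checks their mean against the
chance band).

## Known limitations

The synthetic AUCs say nothing about performance on real slides; the
pipeline has no stain normalization (the source protocol does not describe
any); pyramid WSI formats are out of scope (inputs are raster arrays/PNG);
and the multivariable model treats age as continuous and the published
category references (male, T3, N0, CEA normal) as fixed.
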