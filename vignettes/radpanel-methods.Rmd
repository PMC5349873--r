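---
title: "radpanel: models, design choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{radpanel: models, design choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`radpanel` packages a complete quantitative-imaging workflow for grading
cystic pancreatic lesions (high-grade vs low-grade IPMN) from ROI-masked
3D volumes. This vignette documents the statistical models, the parameters
that matter, what the synthetic-data generator does and does not emulate,
and the places where the design was genuinely open and a choice had to be
made.

## 1. Texture model

Voxels inside the ROI are quantized by equal-width binning over the ROI's
own min–max range (default `levels = 32`); the maximum maps to the top
level and a constant ROI maps everywhere to level 0. Binning over the
ROI's own range rather than a global calibration isolates *texture* from
absolute intensity: any strictly increasing gray-value transform that
preserves bin assignments leaves every GLCM feature unchanged, which is
also a tested invariant.

For an integer direction `(dx, dy, dz)` and distance `d`, the GLCM
accumulates counts over voxel pairs `(v, v + d·(dx,dy,dz))` with **both**
endpoints inside the mask, symmetrically by default (each pair counted in
both orders, standard Haralick practice, which halves the direction set to
the 13 unique 3D directions, or 4 in-plane for 2.5D). Because a 2.5D
offset has `dz = 0`, in-plane pairs never cross slices and per-slice
accumulation with pooling is algebraically identical to the volumetric
pass; the two modes therefore share one code path and differ only in the
admissible direction set and naming. Counts are normalized to a joint
probability matrix; a spec with no valid in-mask pair raises a dedicated
`radpanel_no_pairs` condition and the feature is recorded as *missing*,
never as zero.

Default distances are 1, 4 and 7 voxels. The feature columns are named
systematically `GLCM{3|25}_{dx}{dy}{dz}-{distance}_{statistic}`. This is a
deliberate *replacement* naming scheme: the direction-code conventions of
legacy feature extractors are not recoverable or portable, so the offsets
are spelled out instead.

Degenerate case: when a marginal SD of the GLCM is zero (homogeneous
region) the correlation statistic is undefined; `radpanel` returns the
sentinel 1.0 — a homogeneous region is treated as perfectly
spatially correlated, matching common implementations and keeping feature
tables rectangular. First-order kurtosis is reported non-excess (Gaussian
= 3) and is missing for fewer than 4 voxels or zero variance.

Markers that are missing for *any* subject are dropped with a warning
rather than imputed: screening a marker on a silently varying subset of
subjects would change its `n` per marker.

## 2. Screening statistics

* **AUC** is the Mann–Whitney estimator with half-credit for ties.
  Markers with raw AUC < 0.5 are flipped (scores negated) before ranking
  and the flip is recorded; orientation handling has to be explicit
  because a correlation feature can legitimately run in either direction.
* **ROC curves** are empirical step functions with the rule
  "score ≥ threshold ⇒ positive", thresholds at observed values only and
  no interpolation; the trapezoidal area equals the Mann–Whitney AUC to
  1e-12 (tested on random data).
* **ROC(0.05)** is the maximum TPR over operating points with empirical
  FPR ≤ 0.05 — with ~19 negatives the achievable FPR grid is coarse, and
  the step-function convention (no interpolation) keeps it reproducible.
* **Youden maximum** ties are broken toward higher specificity, then the
  higher threshold: clinically conservative (fewer false surgeries).
* **P-values** use the normal approximation to the Mann–Whitney U
  statistic with tie-corrected variance, *not* bootstrap inference: the
  screening regime needs p-values far below the 1/draws resolution of any
  practical bootstrap. At n = 34/19 the type-I error at α = 0.05 is
  calibrated to [0.03, 0.07] (tested by simulation). All-tied scores
  return p = 1.
* **FDR** is Benjamini–Hochberg step-up. The procedure choice was open
  (the workflow this models names no method); BH is the field default for
  marker screening.
* **Bootstrap CIs** are percentile intervals from resampling stratified
  within class — with a 34/19 imbalance an unstratified draw frequently
  loses the minority class. Percentile is the simplest method consistent
  with a refit-per-draw design; BCa-style corrections are out of scope.

Candidates for the panel are the union of the top-10 markers by AUC and
the top-5 by ROC(0.05) (both configurable), tagged `AUC`, `ROC(0.05)` or
`BOTH` in the report.

## 3. Panel construction

Every non-empty subset of the candidates (hard cap 15, i.e. ≤ 32 767
fits) is fit by maximum-likelihood logistic regression and ranked by
`AIC = 2k − 2ℓ`, `k = 1 + #markers`. Fitting is IRLS (Newton) on
z-scored markers (train-set statistics; predictions are invariant to this
affine rescaling, coefficients are reported on the z-scale), convergence
at max coefficient change < 1e-8 or 100 iterations.

With ~50 subjects and up to 15 candidates, perfect separation is routine
in the larger subsets. Divergence is detected when any standardized
coefficient passes 15 — legitimate ML fits on z-scored markers live well
below that, while separated fits march past it within a few Newton steps.
The subset is then refit with a small L2 penalty (1e-4, scaled by n, on
non-intercept coefficients) and flagged; AIC always uses the unpenalized
log-likelihood at the returned coefficients. The flagged-fallback design
keeps the exhaustive search total instead of silently dropping exactly
the subsets that fit the training data best. AIC ties break toward the
smaller subset, then lexicographic marker names, so runs are
deterministic.

## 4. Validation

Both cross-validation schemes use stratified 2/3–1/3 splits (class
proportions preserved to integer rounding; with 19 LG subjects
unstratified thirds would often be single-class).

* **Scheme 1** (1000 repeats): marker set fixed, coefficients refit per
  split, test-set AUC recorded. Per-split AUCs are averaged; pooling test
  scores across splits is a noted alternative that was not chosen because
  scores from differently-calibrated fits are not exchangeable.
* **Scheme 2** (10 repeats): screening, candidate selection, exhaustive
  search and fitting all run inside the training split; the frozen model
  is applied to the test split. This is the estimate that is honest about
  selection optimism, and the package's tests demonstrate the phenomenon:
  on pure-noise data at n = 34/19 the resubstitution AUC of the selected
  panel exceeds the scheme-2 AUC by ≈ 0.38 on average.
* **Panel bootstrap** (1000 draws): stratified resample, coefficients
  refit per draw (propagating coefficient variance), in-draw AUC and
  Youden J collected, percentile intervals reported. Simulated coverage
  for a designed AUC-0.9 single-marker panel at n = 34/19 is ≈ 93%,
  within the accepted 95% ± 5% band — percentile intervals for AUCs near
  1 are known to undercover slightly.

Failed fits are excluded and counted (CV) or redrawn and counted
(bootstrap), never imputed.

A note on Monte-Carlo error: repeated splits of *one* dataset are
correlated, so "CV AUC ≈ 0.5 under the null" is asserted against the
between-dataset standard error over several simulated cohorts, not the
within-dataset repeat SE.

## 5. PCA view

Markers are z-scored (population SD) and the covariance of the
standardized table is eigendecomposed — i.e. correlation-matrix PCA,
because GLCM correlations, entropies and raw intensities live on
incommensurate scales. Zero-variance markers are dropped with a warning.
Sign convention: each component's largest-magnitude loading is positive.
"The grades separate in the first two components" is quantified as the
between-centroid distance in pooled within-class SD units
(`pca_separation()`), because a visual "distinct pattern" is not a
testable statement; the threshold of ~2 pooled SDs used in the tests is
this package's own acceptance device.

## 6. Fukuoka module

Six flags: main-duct involvement, cyst > 3 cm, mural nodules,
MPD > 5 mm, positive cytology, symptoms; positive = any flag. Size
thresholds are strict inequalities per the criteria's wording ("> 3 cm"),
so a 3.0 cm cyst does not trigger. Main-duct involvement is modeled as a
positivity-triggering flag co-equal with the other five (the alternative
reading — a lesion-type descriptor — would not change the cohort
arithmetic, since those lesions carry other flags in the reference
margins).

The cohort summary reports the *benign fraction among positives*. In an
all-resected, all-Fukuoka-positive cohort the textbook FPR
(FP/(FP+TN)) is degenerate (no negatives exist); the benign-among-
positives fraction (19/53 → 36% at the reference margins) is the only
reading consistent with "operating on benign lesions a third of the
time", and is reported as such.

## 7. The synthetic cohort: what it does and does not emulate

The generator provides the *statistical structure the analysis assumes*,
not pancreas imaging:

* **Textures** are isotropic Gaussian random fields — white noise FFT-
  convolved with a periodic Gaussian kernel of per-class width — rescaled
  to an intensity mean/SD and overlaid with white noise. Defaults:
  34 HG / 19 LG subjects, 24×24×16 voxels, smoothing 2.5 (HG) vs 1.0
  (LG) voxels, identical intensity statistics (mean 100, SD 20, noise
  SD 5) so the class signal is purely textural. The smoothing length is
  the one generative knob that directly moves the GLCM correlation
  statistic. The effect size was verified once at n = 200/class (best
  distance-1 correlation marker AUC ≈ 1.0) before freezing the
  n = 30/class AUC > 0.9 test threshold.
* **ROIs** are centered axis-aligned ellipsoids (semi-axes 0.42 of each
  dimension) with seeded ±10% radius jitter, grown in 5% steps if
  discretization on coarse grids pushes coverage below the 20% floor.
  The jitter prevents features from keying on a fixed mask geometry.
* **Marker tables** use the binormal model: LG ~ N(0,1),
  HG ~ N(δ,1), δ = √2·Φ⁻¹(AUC), with optional inter-marker correlation
  and any number of pure-noise markers.
* **Fukuoka records** allocate criterion flags by a deterministic greedy
  (rarest criterion first to uncovered subjects, remainder to the least-
  flagged, seeded tie-breaks), which reproduces requested per-grade
  margins *exactly* and guarantees every record is criterion-positive
  whenever the margins make that feasible (sum ≥ n). Continuous fields
  are drawn strictly inside/outside their thresholds
  (cyst U(3.1, 6.0) vs U(0.5, 3.0) cm; MPD U(5.5, 10) vs U(1, 5) mm) so
  no boundary ambiguity exists.

Not emulated: pancreas anatomy, Hounsfield calibration, contrast phases,
partial-volume or stent artifacts, inter-scanner variation, and the
intensity distribution of real cysts (the Gaussian-field choice is a
modeling convenience, not a claim about CT physics). A green test on
synthetic data therefore establishes that the *pipeline* is correct and
calibrated — not that any particular clinical effect size is real.

## 8. File formats and reproducibility

Volumes are read/written as single-file NIfTI-1 (`.nii`/`.nii.gz`,
float32 data) by a minimal reader in the package itself; feature tables
and reports are CSV; configs and results are JSON (YAML is intentionally
not supported to avoid an extra dependency). Every stochastic stage takes
an explicit seed; the pipeline expands one root seed into per-stage seeds
(kept below 2³¹), and two runs from the same config produce byte-identical
report files (tested).

## 9. Known limitations

* The GLCM direction/distance grid is voxel-space and ignores anisotropic
  spacing; spacing is carried through as metadata only.
* No DeLong variance, exact permutation p-values, or smoothed/binormal
  ROC fits; no LASSO/stepwise alternatives to the exhaustive AIC search.
* Percentile bootstrap intervals undercover mildly for AUCs near 1.
* The exhaustive search cost grows as 2^|candidates|; the cap of 15
  candidates is a hard design limit, not a tuning suggestion.
* `cv_full_procedure` with few repeats (the default 10) has substantial
  Monte-Carlo spread; the per-repeat AUC vector is returned so users can
  judge it.
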