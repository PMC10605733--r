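---
title: "Spectral detection and tumor morphology for bi-parametric prostate MRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectral detection and tumor morphology for bi-parametric prostate MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bpace)
```

## The problem

Bi-parametric prostate MRI (BP-MRI) acquires three sequences without
contrast injection: the apparent diffusion coefficient map (ADC), a
high-b-value diffusion image (HBV) and a T2-weighted structural image.
Viewed jointly, each voxel is a three-component "spectral" vector, and
a prostate tumor has a characteristic contrast pattern — low ADC, high
HBV, low T2 — against normal prostate tissue.  `bpace` treats the
registered three-channel volume the way remote sensing treats a
hyperspectral cube: a supervised target detector (the Adaptive Cosine
Estimator, ACE) scores every voxel against an in-scene tumor
signature, detections are aggregated into connected blobs, and blob
*volume* and *eccentricity* are used as quantitative markers of tumor
aggressiveness, graded clinically by the ISUP group (0–5; ISUP ≥ 2 is
clinically significant cancer, CsPCa).

The package implements the full chain — synthetic data, registration,
detection, morphology, statistics, orchestration — in plain R, with a
phantom generator providing ground truth so every stage is testable
without any external imaging data.

## Registration and the stitched hypercube

Sequences arrive on different grids (T2 is typically finest in-plane).
The pipeline:

1. **Resample to the lowest resolution.**  The target grid is the
   sequence with the *largest* in-plane voxel area; ties prefer the ADC
   grid, which is the stated reference.  Intensities are interpolated
   bilinearly, masks by nearest neighbour — the standard choice where
   the underlying work is silent.  Slice grids are assumed shared
   across sequences (axially co-planned acquisitions); a slice-count
   mismatch is an error naming the sequences rather than a silent
   resample.
2. **Translate by header offsets.**  The moving sequence is shifted by
   the voxel-rounded difference of header origins; the sub-voxel
   residual is logged.  The original study's manual "visual fine
   alignment" cannot be reproduced programmatically, so it is replaced
   by an explicit per-sequence integer `extra_shift` in the
   configuration, default `(0, 0)`.
3. **Crop to the common field of view** (intersection of valid extents
   after shifting), applied identically to images and masks so voxel
   correspondence is preserved.
4. **Stitch.**  Slices are abutted horizontally into a `rows ×
   (slices·cols)` mosaic per channel, with a per-column slice-index map
   so later stages can always tell which tile a column belongs to.  The
   mapping is exactly invertible (`unstitch()`).

Indexing convention (defined once, in `?sequence_volume`): arrays are
1-based `[row, col, slice]`; `spacing`/`origin` follow header order
`(x, y, z)` in mm; the physical position of voxel `[r, c, k]` is
`origin + (c-1, r-1, k-1) * spacing`.  Voxel volume is the product of
the common-grid spacings, reported in mL.

## ACE detection

Background statistics are the sample mean `m` and sample covariance
`CM` (denominator `n − 1`) of the channel vectors under the
normal-prostate mask.  With `d = x − m` and `t = S − m`, the score is

$$\mathrm{ACE}(x) =
\frac{(t^\top CM^{-1} d)^2}{(t^\top CM^{-1} t)(d^\top CM^{-1} d)},$$

the squared cosine between the whitened test vector and the whitened
signature; the decision surface is a cone around the signature.  Design
choices, each exposed or documented:

* **Squared, centered form.**  The score lives in `[0, 1]`, matching
  the 0.90–0.96 threshold grid; both vectors are centered by the
  background mean, the standard in-scene convention.  The signed cosine
  (`[−1, 1]`) is available via `form = "signed"`.
* **No covariance regularization or principal-component removal** —
  these reportedly did not help at three channels; a singular `CM` is
  an error asking for more mask voxels.
* **Degenerate cases.**  A voxel equal to the background mean scores 0
  (limit convention); a signature equal to the background mean is
  rejected.

With only three channels the null false-alarm rate is substantial
(for Gaussian background the squared cosine is Beta(1/2, 1), so about
5% of background voxels exceed 0.90); the high threshold *and* the
blob-size filter together control false detections.

Thresholding is strict (`score > threshold`), optionally restricted to
the prostate scene mask, and nested: the 0.94 mask is always a subset
of the 0.90 mask.

## Blobs, volume, eccentricity

Blobbing is two-dimensional and per stitched tile: above-threshold
voxels are grouped by 8-connectivity, and connectivity is never
evaluated across tile seams, so a blob always lives in one slice.
Labels are assigned in raster order, which makes volume ties
deterministic.  Blobs with fewer than 5 voxels (about 0.01 mL at
2 × 2 × 3 mm) are discarded.

Per blob, the inertia matrix is the 2 × 2 matrix of second central
moments of the member in-plane coordinates; its eigenvalues `l ≥ s`
are proportional to squared semi-axis lengths, and eccentricity is the
normalized difference

$$E = \frac{l - s}{l + s} \in [0, 1],$$

0 for a disk, 1 for a line; for a dense ellipse with semi-axes
`a ≥ b` it converges to `(a² − b²)/(a² + b²)`, which is the closed
form the tests check against.  The classical conic eccentricity
`sqrt(1 − s/l)` is exposed as `method = "classical"`.  A single-voxel
blob is defined to have `E = 0`.

Three features feed the statistics stage: the largest blob's volume,
the mean blob volume, and the *largest* (maximum-volume) blob's
eccentricity — "max blob eccentricity" is read as the largest blob's
eccentricity, not the maximum eccentricity over blobs.  An empty
detection (common at high thresholds) yields all-zero features plus an
`empty` flag rather than dropping the patient.

Because blobbing is per-slice, a tumor spanning `k` slices appears as
`k` blobs; the max-blob volume tracks the largest single-slice
cross-section.  Whether the original analysis merged blobs across
adjacent slices is unknown; the per-tile behaviour is implemented and
flagged here.

## Cohort statistics

* `fit_univariate(x, y)`: OLS with signed Pearson `R`, slope t-test
  `p`, 95% CIs and the overall F probability.
* `fit_multivariate(x1, x2, y)`: joint OLS.  `R1`, `R2` are *signed
  univariate* Pearson correlations of each predictor with the grade,
  while their parenthesized p-values come from the *joint* fit's
  coefficient t-tests; `R12 = sqrt(R²)` of the joint fit and the
  F-statistic probability summarize the pair.  This mixed reading is
  the only one consistent with the published table layout this
  structure mirrors.
* `roc_auc`: trapezoidal integration over distinct score values, which
  equals the Mann–Whitney pair-counting probability with ties worth
  one half (the test oracle enumerates pairs exhaustively).
* `logistic_split_auc`: 70%/30% random splits, 1000 by default, each
  fitting an unpenalized ML logistic model on the training part and
  scoring the held-out part; the AUC distribution is summarized by its
  mean (the point statistic is otherwise undefined) and the 2.5/97.5
  percentile interval.  Splits whose training or test part lacks a
  class are redrawn and counted — safer than scoring them 0 — and a
  cohort with fewer than two patients per class is an explicit error,
  reported as NA in sweep tables.  Perfectly separable training folds
  are left to `glm`'s finite-but-large ML coefficients; the induced
  ranking (hence the AUC) is well defined.
* `threshold_sweep`: one row per (threshold, feature) with R, p and
  AUC + CI; the optimal threshold per feature is the argmax of R.  No
  multiple-testing correction is applied across thresholds or
  features, matching the original analysis.

## The synthetic world

`phantom_spec()` describes one study: three grids sharing a slice
stack (defaults 2 × 2 mm ADC/HBV, 0.5 × 0.5 mm T2, 3 mm slices), a
prostate ellipsoid filled with correlated multivariate-Gaussian
background, and elliptical-cylinder tumors (in-plane semi-axes
`a ≥ b`, rotation, slice extent) with analytic truth: volume
`π·a·b·h`, eccentricity `(a² − b²)/(a² + b²)`.  Tumors are defined in
physical mm and rasterized per grid, so registration tests have
sub-voxel truth.  One underlying three-channel field is sampled on the
coarsest grid and observed by each sequence, so cross-channel
correlation survives registration; the T2 acquisition offset is
applied to the voxel content with the compensating origin recorded in
the header, exactly the situation header-driven alignment must undo.

Default intensities are illustrative, not physiological (no published
intensity statistics exist for the source collection), and are fully
configurable: background mean `(1200, 150, 400)` with standard
deviations `(120, 30, 60)` and mild cross-channel correlation; tumor
mean `(650, 420, 180)`, giving the `(−, +, −)` contrast pattern for
(ADC, HBV, T2).  The background is Gaussian because the detector is
defined by second-order statistics; Rician noise, bias fields, motion
and DCE synthesis are deliberately out of scope.  A green test
therefore establishes correctness of the *algorithms* under the
stated model, not clinical performance on real scanners.

`cohort_spec()` adds the latent grade model
`ISUP = clamp(round(β0 + βV·V + βE·E + ε), 0, 5)`, with `V` the
largest tumor's true volume (mL) and `E` its true eccentricity —
the simplest model producing the monotone relationships the
statistics layer must recover (`βV > 0`, `βE < 0` enforced).
Defaults `β0 = 0.4`, `βV = 1.2` per mL, `βE = −1.5`, `σ = 0.6` were
chosen once so that a typical cohort reproduces the shape of the pilot
cohort's grade histogram (mostly ISUP 0–1, few high grades) with
tumor volumes in the 0.1–4 mL range; they were not adjusted
afterwards.  Clinical covariates (age, PSA, prostate volume) are drawn
independently of grade, mirroring the weak clinical-variable
correlations in the pilot data.

The test suite and acceptance checks run the cohort machinery on a
scaled-down grid (64 mm field of view, 6 slices, T2 at 1 mm) purely
for runtime; the parameter-recovery world is fixed at n = 60 patients,
`βV = 2`, `βE = −2`, `σ = 0.3`, threshold 0.90, 20 seeded replicates.

## Numerical choices and degenerate inputs

* ACE quadratic forms use the Cholesky inverse of `CM`; scores are
  clamped to `[0, 1]` against floating-point overshoot.  The
  implementation must agree with an independent whiten-then-cosine
  oracle to 1e−10.
* Non-integer header shifts are rounded to the nearest voxel and the
  residual logged (sub-voxel resampling is deliberately avoided at
  this stage).
* Blob labeling uses two-pass union-find; the test oracle is an
  independent BFS flood fill; equality is exact.
* Empty blob lists, tumor-free phantoms, single-class cohorts and
  degenerate splits all take defined, logged paths rather than
  erroring mid-cohort; a corrupt patient is recorded and skipped.
* All randomness flows through explicit seeds (`phantom_spec`,
  `cohort_spec`, `logistic_split_auc`), restored on exit, so identical
  seeds give byte-identical outputs.

## Known limitations

* Per-slice blobbing means multi-slice tumors are measured by their
  largest cross-section, not their 3-D volume.
* The MetaImage/NIfTI readers cover the axis-aligned, uncompressed,
  little-endian single-file variants the package writes (validated
  against an independent Python reader); rotated or gzipped volumes
  are not supported.
* The eccentricity of small blobs (a few voxels) carries substantial
  discretization error; tolerance-sensitive comparisons should use
  blobs at least ~5 voxels across, as the tests do.
* The synthetic world omits MR physics; quantitative agreement with
  real-cohort results is out of scope by design.
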