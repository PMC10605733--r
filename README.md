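# bpace

Spectral target detection and tumor morphology for bi-parametric
prostate MRI.

## What this package does

Bi-parametric prostate MRI (BP-MRI) combines three contrast-free
sequences — the apparent diffusion coefficient map (ADC), a
high-b-value diffusion image (HBV) and a T2-weighted image.  Treating
each voxel as a three-component spectral vector, `bpace`:

1. **registers** the three sequences onto a common grid (resample to
   the coarsest in-plane resolution, translate by header offsets, crop
   to the shared field of view) and **stitches** the slices into a
   three-channel mosaic hypercube;
2. **detects** tumor-like voxels with the Adaptive Cosine Estimator
   (ACE).  With background mean `m`, background covariance `CM`
   (estimated over a normal-prostate mask), in-scene signature `S`,
   `d = x − m` and `t = S − m`:

   ```
   ACE(x) = (tᵀ CM⁻¹ d)² / [(tᵀ CM⁻¹ t)(dᵀ CM⁻¹ d)]  ∈ [0, 1]
   ```

   the squared cosine between the whitened voxel and whitened
   signature; the decision surface is a cone around `S`;
3. **measures morphology**: thresholded voxels are grouped into
   in-plane 8-connected blobs (never across stitched-tile seams),
   blobs under 5 voxels are filtered out, and each blob gets a volume
   (voxel count × voxel volume, mL) and an inertia-eigenvalue
   eccentricity `E = (l − s)/(l + s)` (0 = round, 1 = line);
4. **relates features to pathology**: per-threshold linear fits of
   max/average blob volume and max-blob eccentricity to the ISUP grade
   (signed Pearson R, p-values, F probability) and repeated-split
   (70/30 × 1000) logistic ROC/AUC against clinically significant
   cancer (ISUP ≥ 2), with 2.5/97.5-percentile confidence intervals;
5. ships a **synthetic phantom and cohort generator** with analytic
   ground truth (tumor volume `π·a·b·h`, eccentricity
   `(a² − b²)/(a² + b²)`, a latent ISUP model with positive volume and
   negative eccentricity effects), so the entire pipeline is testable
   without any external data.

It is aimed at researchers studying quantitative BP-MRI markers of
prostate tumor aggressiveness and at anyone who wants a tested,
self-contained reference implementation of the ACE →  blob →
regression pipeline.

## Worked example

A phantom study with one tumor (semi-axes 9 × 5 mm, one 3 mm slice,
rotated 0.5 rad) whose T2 was acquired with a +2-voxel offset recorded
in its header:

```r
library(bpace)
tumors <- data.frame(cx = 52, cy = 46, a = 9, b = 5, theta = 0.5,
                     slice_first = 4, slice_count = 1)
spec <- phantom_spec(tumors = tumors, t2_offset_vox = c(2L, 0L), seed = 7)
ph <- generate_phantom(spec)
ph$truth[, c("volume_mL", "eccentricity", "n_voxels")]
#>   volume_mL eccentricity n_voxels
#> 1  0.424115    0.5283019       36

res <- run_patient(ph, run_config())
res$features[, c("threshold", "max_blob_volume", "max_blob_eccentricity", "n_blobs")]
#>  threshold max_blob_volume max_blob_eccentricity n_blobs
#>       0.90           0.444             0.5236268       1
#>       0.92           0.444             0.5236268       1
#>       0.94           0.444             0.5236268       1
#>       0.96           0.432             0.5339277       1
```

The detected max-blob volume (0.444 mL) is within 5% of the analytic
truth (0.424 mL) and the measured eccentricity (0.524) within 0.005 of
the truth (0.528) — registration undid the header offset, ACE found
the tumor voxels, and the moment computation recovered the shape.

A 20-patient cohort with the default latent grade model
(`β_V = 1.2 > 0`, `β_E = −1.5 < 0`):

```r
base <- phantom_spec(fov_mm = c(64, 64), n_slices = 6, slice_mm = 3,
                     spacing = list(ADC = c(2, 2), HBV = c(2, 2), T2 = c(1, 1)),
                     prostate_center = c(32, 32, 9),
                     prostate_semiaxes = c(22, 18, 9), seed = 0)
co <- generate_cohort(cohort_spec(n = 20, base_spec = base, seed = 42))
cres <- run_cohort(co, run_config(reps = 200, seed = 42))
subset(cres$univariate, threshold == 0.90)
#>  threshold               feature      r       p   auc ci_lo ci_hi
#>        0.9       max_blob_volume 0.6347 0.00264 0.912 0.625     1
#>        0.9       avg_blob_volume 0.5675 0.00906 0.900 0.600     1
#>        0.9 max_blob_eccentricity 0.0189 0.93683 0.738 0.374     1
```

Volume features correlate positively with grade (R = 0.63, p = 0.003)
and separate significant from insignificant cancer (mean split-AUC
0.91); `attr(cres$univariate, "optimal")` reports the
highest-correlation ("optimal") threshold per feature.

## Command line

```sh
BPACE_CLI=$(Rscript -e 'cat(system.file("cli", "bpace.R", package = "bpace"))')
Rscript $BPACE_CLI simulate --n 10 --seed 1 --out cohort/
Rscript $BPACE_CLI run-all --in cohort/ --out report/ --reps 200
Rscript $BPACE_CLI run-all --n 10 --out report/ --thresholds 0.90,0.94
```

Subcommands: `simulate`, `register`, `detect`, `blobs`, `stats`,
`run-all`; exit code 2 flags configuration errors, 1 data errors.
Volumes are read and written as uncompressed MetaImage (`.mha`) or
NIfTI-1 (`.nii`); tables as CSV.

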