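# vitreoct

Quantification of anterior (retrolental) vitreous opacification in 3-D
swept-source OCT volumes.

The vitreous gel liquefies and its collagen aggregates with age; the
resulting fibrous opacities scatter light and degrade contrast
sensitivity. With the focal plane behind the crystalline lens and the
zero delay line near the vitreous, SS-OCT resolves the 2-mm slab of
vitreous just behind the posterior lens capsule. `vitreoct` turns such
volumes into numbers, for imaging scientists and vision researchers who
need a reproducible, testable pipeline rather than one-off scripts:

* **Eye-motion correction.** Axial: the posterior capsule is delineated
  per A-scan (Sobel of Gaussian-blurred cross-sections, sub-pixel
  refinement), a paraboloid `z = c0 + c1 x + c2 y + c3 x^2 + c4 y^2` is
  fitted, and each B-scan is shifted by the rounded median of
  (detected − fitted) depth. Transverse: the pupil is masked in the en
  face projection and B-scans are shifted to restore a circular pupil.
  Shifts are integer pixels; intensities are never interpolated.
* **Segmentation.** Crystalline lens = space between the fitted anterior
  and posterior capsules; anterior vitreous = the 2-mm slab behind the
  posterior capsule; both limited to the pupil.
* **Indices.** With linear-scale intensities I and dB = 10·log10(I):

  - `VOD = 10·log10( mean(I) over the vitreous slab )` (au)
  - `LOD = 10·log10( mean(I) over the lens )` (au)
  - `VOR = |{ v in slab : 10·log10(I_v) > 78 dB }| / |slab|` in [0, 1]

  plus a depth-coded maximum intensity projection of the slab.
* **CSF.** `AULCSF` = trapezoidal area under log10(CS) versus
  log10(spatial frequency).
* **Statistics.** One-way random-effects ICC(1) with Searle 95% CIs,
  Pearson correlations with Fisher intervals, LOESS-vs-linear residual
  comparison, axial-length-stratified group tests gated by Shapiro–Wilk,
  Tukey ladder of powers, forward stepwise regression (AIC) with
  standardized β and adjusted R², one random eye per subject.

Raw clinical scans cannot be shipped, so the package includes a synthetic
phantom generator (capsule geometry, iris/pupil, gel, fibrous opacities,
lacunae, laminae, Berger's space, speckle with exponential marginals,
depth roll-off, per-B-scan eye motion) with complete ground truth, and a
cohort generator with realistic covariate distributions. Every pipeline
stage is validated against these; see the methods vignette
(`vignettes/vitreoct-methods.Rmd`) for the models, conventions, and
limitations.

## Worked example

Simulate a motion-corrupted phantom, correct it, segment it, quantify it:

```r
library(vitreoct)

spec <- phantom_spec(
  shape = c(100L, 120L, 400L), spacing = c(8/300, 8/300, 0.008),
  anterior  = list(apex_z = 60,  apex_xy = c(3, -2), curv =  0.005),
  posterior = list(apex_z = 150, apex_xy = c(4, -3), curv = -0.008),
  pupil_radius_mm = 51 * 8/300, iris_offset_px = 40, iris_thickness_px = 12,
  n_fibers = 10, fiber_length_px = 80, n_lacunae = 1,
  lacuna_axes_px = c(7, 7, 18), slab_thickness_mm = 1.5,
  motion = list(axial_sd_px = 2, n_jumps = 1, jump_amp_px = 5), seed = 7)

ph  <- make_phantom(spec)        # $volume, $moving, $truth
mc  <- correct_motion(ph$moving)
seg <- segment_volume(mc$volume, slab_thickness_mm = 1.5)
opacity_indices(mc$volume, seg, threshold_db = 78)
#> VOD 63.37 au | LOD 72.54 au | VOR 0.0091 (>78 dB)
ph$truth$vor
#> [1] 0.01389848
```

The recovered motion trace matches the injected one on 100.0% of B-scans
(within 1 px). The measured VOR sits below the geometric truth because
multiplicative speckle pushes a predictable fraction of fiber voxels
below the 78 dB threshold; the test suite checks the observed VOR against
that law exactly.

Cohort-level analysis on a synthetic 49-subject cohort:

```r
co  <- make_cohort(cohort_spec(n = 49, seed = 1))
rep <- analyze_cohort(co, seed = 2)
rep$icc$VOR
#> ICC(1) = 0.962 (95% CI 0.939-0.977), F = 76.01, p = 6.21e-60
rep$correlations[["age~VOR"]]
#> Pearson R = 0.780 [0.639, 0.870], p = 3.85e-11, n = 49
rep$correlations[["VOR~AULCSF"]]
#> Pearson R = -0.574 [-0.736, -0.349], p = 1.6e-05, n = 49
rep$stepwise$AULCSF
#> stepwise model for AULCSF: age + AL + VOR
#>   standardized beta: age = -0.414, AL = -0.314, VOR = -0.233
#>   adjusted R2 = 0.465, model p = 7.15e-07, n = 49
```

ICCs measure replicate reproducibility of the indices; the correlation
signs (index–age positive, VOR–AULCSF negative) reflect the generator's
structural model: opacification rises with age and degrades contrast
sensitivity. `run_pipeline()` chains all stages from one config and
writes a manifest with file hashes for reproducibility.

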