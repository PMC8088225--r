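---
title: "Quantifying anterior vitreous opacification in 3-D SS-OCT: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying anterior vitreous opacification in 3-D SS-OCT: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

The vitreous body is transparent in youth and degenerates with age:
collagen dissociates from hyaluronan, liquefied pockets (lacunae) form, and
collagen aggregates into fibrous opacities that scatter light and degrade
vision. Swept-source OCT at ~1 micron wavelength, with the focal plane
placed just behind the crystalline lens and the zero delay line near the
vitreous, can resolve the retrolental (anterior) vitreous in vivo:
gel vitreous, lacunae, laminar membranes, Berger's space, and fibrous
opacifications all appear in the volumes.

`vitreoct` implements a complete quantification pipeline for such volumes:

1. **Motion correction** of involuntary eye movements, axial and transverse.
2. **Segmentation** of the crystalline lens (between the anterior and
   posterior capsules) and of a 2-mm-thick retrolental vitreous slab.
3. **Opacification indices**: vitreous optical density (VOD), lens optical
   density (LOD), and the vitreous opacification ratio (VOR), plus
   depth-coded maximum intensity projections.
4. **Contrast sensitivity**: the area under the log-log contrast
   sensitivity function (AULCSF).
5. A **statistical layer**: one-way random-effects ICC for replicate
   reproducibility, Pearson correlations with Fisher intervals, LOESS
   versus linear residual comparison, axial-length-stratified group tests
   with Shapiro-Wilk gating, the Tukey ladder of powers, and forward
   stepwise regression with standardized coefficients.

Because raw clinical scans are not distributable, the package ships a
**synthetic phantom and cohort generator** with complete ground truth;
every stage of the pipeline is validated against it.

## Conventions

Volumes are arrays indexed `[b, a, z]`: b the B-scan (slow) axis, a the
A-scan (fast) axis, z depth, with z = 1 at the zero delay line and depth
increasing away from the instrument. Default voxel pitch is 8/300 mm
laterally and 8/1200 mm axially (an 8 x 8 x 8 mm field in 300 x 300 x 1200
voxels). The axial pitch is treated as geometric distance; whether the
instrument's pitch is optical or geometric is not resolvable from image
data alone, and a refractive-index rescaling would only rescale the slab
thickness in voxels.

Intensities are linear-scale and non-negative; decibel values use
`10*log10(I)` with a unit reference. This single scale makes the three
quantities mutually consistent: VOD and LOD are the dB of the ROI mean
(averaging done in linear scale, as it must be for speckled intensities),
and VOR thresholds single voxels at 78 dB on the same axis. Whether
published "au" values for such indices are linear means or dB of means is
ambiguous in general; the dB-of-mean convention was chosen because it
places typical vitreous (~32 au), lens (~70 au) and the 78 dB opacity
threshold on one coherent scale. The reference is configurable.

Stored volumes are 32-bit float multi-page TIFFs (one page per B-scan)
with a JSON sidecar carrying shape, spacing, scale and free-form metadata.
The TIFF writer stores samples in [0, 1], so intensities are divided by a
recorded power-of-two factor before writing: a power-of-two scaling is
exact in binary floating point, so write/read round trips are bit-exact at
float32 precision (the constructor snaps intensities to float32 for this
reason).

## The phantom generator

`phantom_spec()` / `make_phantom()` build an anterior-segment scene from
explicit geometry and reflectivities, then apply the physics-inspired
degradations. All generation is a pure function of the spec and its seed.

**Geometry.** Both capsule surfaces are axis-aligned paraboloids
`z = apex + curv * ((x - x0)^2 + (y - y0)^2)` in centred pixel
coordinates; the anterior curvature is positive (apex nearest the
instrument), the posterior negative. The pupil is a disk; outside it an
iris band occludes everything deeper. Defaults place the capsules so that
the standard 2-mm slab fits the grid.

**Tissue reflectivities (dB).** aqueous 20, gel vitreous 32, lens 73,
capsule lines 88 (1-voxel specular lines), iris 55, fibers 82, lacuna
shells 82, laminae 70. The gel and lens defaults land the noise-free VOD
and LOD near the magnitudes such indices take in practice; fibers sit
above the 78-dB opacity threshold and gel far below it, so ground-truth
VOR is controlled by morphology. The quantitative morphology (fiber
diameter and length, lacuna axes) is not published anywhere; defaults are
visually calibrated to the qualitative descriptions (fiber networks
surrounding extremely hyporeflective lacunae; laminae that do not span the
whole pupil) and are configuration, not measurements.

**Morphology.** Fibers are smoothed 3-D random-walk tubes confined to the
retrolental slab with a small stand-off behind the capsule; lacunae are
zero-intensity ellipsoids ringed by a bright fibrous shell; laminae are
thin membranes (flat, plicated, or corrugated) a configurable distance
behind the posterior capsule; an optional hyporeflective Berger-space gap
separates capsule and gel.

**Speckle and noise.** Fully developed speckle is the squared modulus of a
circular complex Gaussian field, which has Exp(1) marginals whatever its
spatial correlation. The complex field is smoothed along depth with a
1-px Gaussian (the coherent axial PSF, ~9 um, slightly exceeds the
6.7 um axial pitch), giving speckle its physical grain; the fast axis is
left uncorrelated, a simplification that favours the edge detector's
averaging. Multiplying clean intensity by this field and adding a
half-normal noise floor yields the observed volume. Sensitivity roll-off
multiplies intensity by `10^(-r*z_mm/10)` with r = 6/11 dB/mm (-6 dB at
11 mm).

**Ground truth.** The truth object records the injected motion trace, the
capsule coefficient vectors, the pupil, the lens/slab masks (built with
the same rules the segmentation module uses), the clean pre-speckle
volume, and the true indices. The true opacity voxel set is defined as the
slab voxels whose clean intensity exceeds the threshold, so on a clean
phantom the computed VOR equals the true VOR identically.

**Motion model.** Axial motion is a per-B-scan Gaussian random walk (slow
drift at the ~75 Hz B-scan rate); transverse motion consists of a few
non-overlapping saccades - constant lateral offsets lasting ~10% of the
volume, at least 5 B-scans apart (saccades have a refractory interval) -
with integer-pixel amplitudes. The component of an axial trace that is
quadratic along the slow axis is exactly absorbed by any paraboloid fit
to the capsule and is therefore indistinguishable from lens shape; the
generator removes this unidentifiable component from its walks by
default (`detrend = TRUE`), which is a gauge choice, not a physical
claim.

## Motion correction

Transverse correction runs first: lateral shifts displace the capsule
surface sideways, which would bias the axial residuals by the local
surface slope. The pupil is detected on the en face projection over the
iris depth band (tracked per B-scan from the lateral border columns, so
uncorrected axial motion cannot move the iris out of the band), Otsu
thresholded; the largest dark component is the pupil, and a circle is fit
to its boundary. Each B-scan is shifted so its pupil-chord midpoint (the
midpoint of the largest contiguous dark run) aligns across B-scans. Two
conventions matter: the zero of the shifts is the majority (median)
midpoint - the circle centre itself is dragged by the displaced B-scans -
and single-B-scan excursions are suppressed (a saccade spans several
B-scans). If the proposed shifts would decrease pupil circularity the
stage falls back to the identity.

Axial correction delineates the posterior capsule per A-scan: Sobel
derivative along depth of the Gaussian-blurred B-scan (sigma 2 px; the
method names the filters but no kernel sizes), anterior line = first
strong rising edge, posterior = strongest edge at least 40 px deeper,
each line refined to sub-pixel precision by a log-domain parabolic
interpolation of the blurred intensity peak (a Gaussian-blurred specular
line is exactly parabolic in log intensity). A second pass re-detects
each surface inside a +-6 px window around a trimmed paraboloid fit,
with per-B-scan window centres taken from the lower quartile of the
row's inlier residuals - the capsule is the shallowest consistent
interface, whereas everything that can capture a row (fiber bundles,
lacuna shells) lies behind it.

Shifts are then estimated from a joint linear model: depth(b, a) =
offset_b + c1 x + c3 x^2, solved by within-B-scan demeaning, with one
MAD-trimmed re-pass. The offsets' quadratic-in-b component is projected
out (the gauge above), and the remaining smooth sub-pixel error - whole
pixels being the only physical shifts - is removed by snapping the gauge
to the integer lattice and subtracting a running-median of the
fractional parts. Shifts are integer pixels and intensities are never
interpolated, so ROI statistics of interior regions are invariant under
correction. `correct_motion()` runs a second axial pass by default;
correction is idempotent, so it is a no-op when the first pass was exact.

## Segmentation and indices

Lens interfaces reuse the delineation machinery with depth-window gating
and must not cross inside the pupil. ROIs: the lens mask spans the space
between the fitted capsules; the vitreous slab starts one voxel below the
posterior capsule (excluding the specular line from vitreous statistics)
and extends `round(slab_mm/dz)` voxels (300 for 2 mm at the default
pitch). Laterally both ROIs are limited to the fitted pupil circle eroded
by 2 px, since the iris blocks deeper propagation; Berger's space and
laminae are *not* excluded - the slab is purely geometric. Slab voxels
beyond the grid are dropped and reported as a coverage fraction; below
50% coverage the zero-delay placement is deemed inadequate and an error
is raised.

VOD/LOD are `10*log10(mean(linear intensity over ROI))`; VOR is the
fraction of slab voxels strictly above the threshold (default 78 dB),
applied per voxel with no smoothing. The depth-coded MIP takes, per
lateral position, the maximum slab intensity and the depth of the
maximizing voxel below the local posterior capsule, ties broken at the
shallowest maximum. Replicates are averaged arithmetically (VOD/LOD in
au, VOR as a fraction) and must share the threshold.

## AULCSF

The area under the log-log contrast sensitivity function is the
trapezoidal integral of log10(CS) over log10(spatial frequency) across
the measured range. No parametric CSF model is fitted, and log10(CS) is
not floored at zero: samples with CS below 1 contribute negatively, as
measured. The synthetic cohort's CSF curves are a fixed unit shape on a
5-frequency grid (3-24 cpd), scaled per eye so that the trapezoid equals
the eye's target AULCSF; because AULCSF is linear in the log-CS scale,
the module recovers the target identically, which links the CSF module to
the cohort generator in the tests.

## The statistical layer

* **ICC(1)**: one-way random-effects intraclass correlation
  `(MSB - MSW) / (MSB + (k-1) MSW)` from the ANOVA mean squares, with
  Searle F-bounds for the 95% CI. This is the single-rater one-way form
  matching a random-effects one-way ANOVA, not the two-way ICC(2,1)/(3,1).
* **Pearson correlation** via the product-moment estimate with a Fisher-z
  interval; no multiple-testing correction is applied anywhere (alpha =
  0.05 per test), by design.
* **LOESS comparison**: degree-2 LOESS (tricube weights, span a fraction
  of the points) versus a straight line, compared by residual standard
  error; the LOESS RSE uses n minus the trace of the smoother matrix as
  its degrees of freedom, the linear fit n - 2.
* **Group comparison** stratified by axial length (nonmyopic AL < 23 mm
  vs myopic AL > 25 mm): Shapiro-Wilk at 0.05 per group, Welch t-test if
  both pass, Mann-Whitney otherwise; summaries follow the same gate
  (mean +- sd vs median (Q1-Q3)).
* **Tukey ladder of powers**: the power maximizing Shapiro-Wilk W over a
  grid (-2 to 2, step 0.025), with the monotone convention `x^l` for
  l > 0, log(x) at 0, `-x^l` for l < 0, and a positivity shift when
  needed.
* **Forward stepwise regression** by AIC from the empty model (the
  criterion is a convention; AIC is the default of the standard stepwise
  implementation this module delegates to), candidates restricted to VOD,
  VOR, LOD, age, AL, AULCSF to limit collinearity; standardized betas are
  `b * sd(x)/sd(y)`; adjusted R-squared from the final fit. Non-normal
  variables are ladder-transformed before modelling.
* **One eye per subject** is selected uniformly at random (seeded) before
  any inference, avoiding bilateral correlation.

`analyze_cohort()` chains all of the above into one report.

## The synthetic cohort

`cohort_spec()` draws ages from a truncated normal (mean 40.0, sd 19.3,
range 9-78 years), axial length from a clipped normal (23.90 +- 1.05 mm,
range 22.06-26.16), and sphere/cylinder similarly. The structural model
is deliberately simple and monotone: LOD linear in age (spanning roughly
50-95 au over the age range); an opacity fraction logistic in age driving
VOR; VOD linear in VOR; OSI linear in VOR and AL; AULCSF linear in OSI -
each with a configurable noise sd, plus between-eye and replicate noise
(the latter sets the ICCs). All coefficients are synthetic defaults
chosen once so that the generated indices land in realistic ranges and
the cohort reproduces the qualitative sign structure (age-LOD, age-VOD,
VOD-VOR positive; VOR-AULCSF negative; higher OSI in myopic eyes) at
n = 49; they are not estimates from any real cohort, and passing tests on
this cohort shows internal consistency of the pipeline, not clinical
validity.

What the generator does *not* emulate: optical aberrations and defocus,
confocal gating, dispersion, the double-pass PSF physics behind OSI
(OSI is consumed as a covariate only), psychophysical staircases behind
CSF samples, and correlated morphology between eyes beyond a shared
subject-level mean.

## Numerical choices and edge cases

* Edge detection floors: an edge must exceed 6x the A-scan's median
  absolute gradient; on a structureless volume nothing passes and
  delineation fails with fewer than 10% of in-pupil A-scans detected.
* Paraboloid fits use one round of MAD trimming (3.5 scaled MADs);
  rank-deficient designs (collinear points) are an error, as are fewer
  than 6 points.
* Degenerate pupil projections (no contrast) return the whole field with
  a `degenerate` flag and a warning rather than an error.
* ICC on zero-variance data is flagged `degenerate` with NA estimates.
* The Tukey ladder rejects constant input; collinear stepwise candidate
  pairs (|r| = 1) are an error naming the pair.
* MIP tie-break: shallowest maximum; empty slab columns are NA.

## Round-trip study geometry

The motion round-trip validation (tests and acceptance script) uses a
150 x 180 x 600 phantom with a 2.05-mm pupil. The fast axis is wider
than the slow axis and the pupil covers every B-scan row, for two
identifiability reasons established during development: per-B-scan axial
shifts are only estimable on rows that cross the pupil (rows without
pupil would tilt the quadratic gauge through their extrapolated
offsets), and lateral jumps need iris margin on the fast axis, otherwise
the pupil chord truncates against the volume edge and midpoints are
uninformative. Problem sizes elsewhere (80 x 80 x 320 unit-test
phantoms, 120 x 120 x 480 segmentation-recovery phantoms, 20-seed Monte
Carlo loops, a 49-subject cohort) were chosen as the smallest grids on
which the respective property is cleanly expressed.

## Known limitations

* Transverse correction only shifts along the fast axis; slow-axis
  reordering is unobservable from a single volume. Rotational/torsional
  registration and inter-replicate registration are out of scope.
* A constant lateral offset and the quadratic-in-b axial component are
  genuinely unidentifiable; the package fixes both by convention
  (majority midpoint; integer-lattice gauge snapping).
* Capsule detection assumes the capsule outshines nearby structures on
  the majority of each row's lower quartile; pathologies that plaster
  the capsule with dense opacities could defeat it.
* The 1-px-quantised phantom rendering limits per-coefficient curvature
  recovery to a few tenths of a percent at best; coefficient accuracy is
  therefore assessed on the coefficient vector (equivalently, surface
  depth), not coefficient-by-coefficient.
* Real "au" scales, device CSF frequency grids, and quantitative
  morphology are not public; the corresponding defaults are synthetic
  and configurable.
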