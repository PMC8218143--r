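---
title: "PET-guided diffusion tractography: models, parameters, and the digital phantom"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{PET-guided diffusion tractography: models, parameters, and the digital phantom}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petdti)
```

## The problem

In medically refractory focal epilepsy, surgical outcome depends on locating
the epileptic focus. When structural MRI is negative, interictal FDG-PET is
the most sensitive non-invasive tool: the focus typically appears as a region
of reduced glucose uptake relative to the homologous contralateral cortex.
`petdti` implements a two-part analysis: (1) voxel-wise hemispheric
*asymmetry-index* (AI) mapping of PET to detect and delineate the
hypometabolic focus, and (2) *PET-guided tractography*, which grows seed
regions into the white matter (WM) at graded distances from the focus, tracks
fiber bundles there and at the mirrored contralateral location, and
quantifies the ipsilateral/contralateral asymmetry of bundle metrics as a
read-out of WM integrity around the focus.

Everything operates in one shared template-like coordinate space (world mm,
RAS, sagittal midplane at x = 0 by construction of the grids). Spatial
normalization, DWI artifact correction and tissue segmentation are upstream
of this package: it consumes spatially normalized PET, tissue probability
maps and DWI.

## Asymmetry mapping

The PET chain is, in order:

1. **SUV**: `SUV = C_PET * BW / Dose`, with activity in Bq/mL, body weight in
   g, injected dose in Bq (unitless under the 1 g/mL convention).
2. **Smoothing**: Gaussian, FWHM 2 mm (per-axis sigma = FWHM / 2.355 /
   voxel size; reflect boundary, which preserves the total signal of
   compact sources). Whether smoothing precedes or follows GM masking is
   configurable (`suv$smooth_before_mask`); smoothing first is the default.
3. **GM restriction**: only voxels with GM probability >= 0.30 (inclusive)
   enter the analysis — the focus is cortical, and WM/CSF voxels would
   dilute the asymmetry statistics.
4. **Cerebellar normalization**: division by the mean SUV over cerebellar
   GM (an explicit mask input; no atlas lookup), removing global-metabolism
   differences. The mean SUVr over the reference region is 1.
5. **AI**: `AI = (I - fI) / (2 (I + fI)) * 100`, where `fI` is the sagittal
   reflection of the SUVr image `I`. AI is antisymmetric and bounded in
   (-50, 50); voxels where `I + fI = 0`, or whose mirror is outside the GM
   analysis set, are undefined and excluded from all statistics.
6. **Z_AI**: standardization by the mean and standard deviation of AI over
   GM voxels with defined AI. The *population* form of the standard
   deviation (divide by N) is the default: the GM voxels are treated as the
   reference distribution itself, not as a sample from one. The sample form
   is available (`sd_type = "sample"`); at brain-scale N the difference is
   negligible.
7. **Threshold**: with n subjects, hypometabolism is declared where Z_AI
   falls below the lower-tail Student-t critical value at alpha = 0.05 with
   df = n - 1 (the single-case construction of Crawford and Garthwaite).
   For n = 14, df = 13 and the critical value is -1.77 (2 d.p.).
8. **Focus extraction**: the suprathreshold GM voxels are labelled by
   26-connectivity (configurable) and the largest connected cluster is the
   PET ROI; its hemisphere is assigned by the sign of its centroid's
   world-x relative to the midline.

### The focal-extent floor

A voxel-wise threshold at alpha = 0.05 leaves ~5% of GM suprathreshold under
the *null* — by chance the largest noise cluster always exists, so "largest
cluster" alone can never return a negative finding. We therefore
operationalize "focal" with a minimum cluster extent: clusters below
`min_roi_voxels` (default 40 voxels, about 0.32 mL at 2 mm isotropic) do not
count as a focus. The default was fixed by a null simulation of the
symmetric phantom at the default noise level: the largest chance cluster
over 50 null datasets was 13 voxels (95th percentile 12), so 40 voxels
controls the family-wise false-positive rate with a ~3x margin while
remaining an order of magnitude below the lesion clusters the pipeline is
meant to find (hundreds of voxels). Detection at this margin fails only for
lesions smaller than ~0.3 mL, which is below what visual PET reading
resolves either.

## Diffusion modelling and tracking

Tensors are fit per voxel to `S_i = S0 exp(-b_i g_i' D g_i)`. The log-linear
system gives the starting estimate; the default `nonlinear_ls` method
refines it by damped Gauss-Newton least squares on the exponential model,
which removes the log-transform's noise re-weighting (the refinement's
eigenvalue RMSE is never worse than the log-linear fit's under Rician noise;
both are exact on noise-free data). Fitting is restricted to WM-weighted
voxels (probability >= 0.25 by default). FA follows the standard eigenvalue
formula; negative eigenvalues (possible under noise) are clamped to zero for
scalar maps and counted.

Tracking is deterministic principal-eigenvector streamline integration:
fixed 0.5 mm Euler steps (RK4 available), sign-coherent nearest-neighbour
direction lookup (trilinear interpolation behind a flag), termination on
FA < 0.10, turning angle > 45 degrees, or grid exit; bidirectional halves
joined at the seed; retained length in [10, 250] mm. Seeds are drawn
uniformly inside each seed-region voxel, 8 per voxel, from a dedicated RNG
seed — the only stochastic element, so a run is bit-reproducible. These
values are standard deterministic-tractography settings. In clinical
practice this workflow is often run with spherical-deconvolution
tractography instead; the tracker here sits behind a small interface
(`track_bundle`) precisely so such a backend can be substituted, and no
claim is made that the defaults match any particular clinical tool's.

## Seeding around the focus

A 3 x 3 x 3 mm^3 VOI is placed at the ROI voxel closest to WM (ties broken
toward the ROI centroid, then lowest voxel index — placement is
deterministic). Seed regions at 3, 9 and 15 mm are the sets of WM voxels
(probability >= 0.5) whose centres lie within that Euclidean distance of the
VOI cube: *cumulative* distance balls, so the regions are nested. A
shell-wise mode (disjoint rings) is available for sensitivity analysis.
The contralateral VOI is the reflection of the ipsilateral one about the
midline — an automated, reproducible replacement for the manual placement
a reader would otherwise perform — with an optional snap to the nearest GM
voxel.

## Bundle metrics and statistics

Per bundle: fiber count; mean length; mean FA as the *length-weighted*
average of FA over all segments, sampled trilinearly at segment midpoints
(the natural weighting when "averaged along the length of the tracts" is
not otherwise specified); and mean cross-section = swept volume (unique
voxels visited x voxel volume) / mean length — a dimensional surrogate
(mm^2) for average cross-sectional area, isolated in one function so a
different definition can be swapped in. Ratios are
ipsilateral/contralateral; 1 is symmetric, < 1 an ipsilateral deficit.
Ratios are compared across the three distances with a Wilcoxon signed-rank
test (subjects as pairs): zeros dropped, midranks for ties, exact null
distribution by generating-function convolution for n <= 25 (identical to
enumerating all 2^n sign assignments), tie-corrected normal approximation
beyond. The continuity correction is off by default and available as a flag
(it brings the approximation within ~0.01 of the exact p at n = 15).

## The digital phantom

No patient data are distributed, so every stage is validated against a
ground-truth phantom (`generate_phantom()`). It emulates the statistical
structure the pipeline assumes; its defaults are the package's study
conditions:

* **Geometry**: 64 x 64 x 48 voxels at 2 mm, mirror-symmetric about a
  grid-aligned sagittal midplane; ellipsoidal brain with a CSF shell, a GM
  ribbon, a WM core (logistic tissue-probability transitions ~1.5 mm wide),
  and an inferior GM cerebellar region.
* **PET**: GM-weighted activity (8000 Bq/mL peak; WM 25%, CSF 5% of GM),
  one spherical GM lesion (default centre mid-GM left, radius 12 mm) scaled
  by `1 - hypometabolism_fraction` (default 0.15), plus i.i.d. Gaussian
  noise at 5% of the GM peak (SNR 20) — reconstruction-domain PET noise.
* **DWI**: b = 0 plus 64 Fibonacci-sphere directions at b = 1000 s/mm^2,
  signals from a ground-truth tensor field, Rician noise at SNR 30. Two
  mirror-image straight bundles (an arc variant exists) run
  anterior-posterior through the WM: a core with eigenvalues
  (1.7, 0.3, 0.3) x 10^-3 mm^2/s (FA 0.799) inside a 4 mm coherent fringe
  at FA 0.45 (the partial-volume rim of a real tract), embedded in a
  gyrus-like WM sheath so healthy fiber length is uniform along the tube.
  Background WM has FA 0.25 with incoherent orientations — real deep WM is
  never isotropic, and incoherence terminates stray tracks via the angle
  criterion rather than the FA floor. Both bundles carry a baseline
  orientation dispersion of 8 degrees drawn from a *mirror-symmetric*
  random field, so the healthy hemispheres remain exact reflections of each
  other.
* **Degradation**: on the lesion side only, FA is reduced toward
  `(1 - w * fa_deficit_fraction)` (default maximum 20%) and an extra
  orientation dispersion of up to 20 degrees is added, both weighted by
  `w = max(0, 1 - d / 25 mm)` with `d` the distance from the lesion centre
  — damage is strongest in the WM adjacent to the focus and fades with
  distance, which is the phenomenology the distance-graded seeding is
  designed to detect.
* **Cohort**: `generate_cohort()` jitters lesion position (±4 mm),
  hypometabolism (±0.03) and FA deficit (±0.05) across subjects with
  deterministic derived seeds. Full-size phantoms are ~100 MB each, so the
  cohort returns specs plus a ground-truth manifest by default and
  materializes phantoms on demand.

What the phantom does *not* model: scanner physics (attenuation, scatter,
point-spread), cortical folding, crossing fibers, susceptibility
distortion, and physiological asymmetries of real brains. Passing the
phantom suite therefore demonstrates the correctness and sensitivity of the
*computational* chain under its stated assumptions, not clinical
performance on patient data.

## Numerical choices and degenerate inputs

* Sagittal flips are exact index reversals when the midline is
  grid-aligned (all phantom grids are built so), trilinear resampling
  otherwise; mask operations use nearest-neighbour only.
* A perfectly symmetric image has zero AI variance; Z_AI is then undefined
  and the pipeline ends with the clean status "no significant
  hypometabolism" rather than an error. The same status covers the
  no-suprathreshold-cluster and below-extent-floor cases.
* Cluster ordering (size, then smallest linear voxel index) and VOI
  placement tie-breaks are deterministic, so identical inputs give
  identical outputs; tracking randomness is confined to seed jitter under
  an explicit RNG seed, and `run_pipeline()` writes an MD5 manifest that
  reproduces exactly under a fixed configuration and seed.
* Gradient tables require >= 1 b = 0 volume and >= 6 unique directions
  (unique up to sign); b-vector norms are renormalized only within 1e-3.
* Non-positive signals are excluded per voxel from the log-linear fit;
  voxels with fewer than 7 usable measurements fall back to an isotropic
  zero tensor at the voxel's mean signal.

## Problem sizes used in the validation suite

The bundled tests and the acceptance script run, by design, at the
phantom's native study conditions: 50 symmetric null datasets and 50
lesion datasets (PET-only, full 64 x 64 x 48 grid) for the
specificity/recovery rates, and one 14-subject degraded cohort with full
DWI synthesis, tensor fitting and tractography per subject. Unit tests use
miniature 16^3 and 32 x 32 x 24 fixtures and small analytic tensor fields.

## Known limitations

* The tensor tracker is a substitute for spherical-deconvolution
  tractography by design; in tissue with crossing fibers a single-tensor
  principal direction is biased, and the phantom deliberately contains no
  crossings.
* The mean cross-section definition is a surrogate; its absolute values
  should not be compared against other tools, only its ipsi/contra ratio.
* Contralateral VOI placement by strict reflection assumes the analysis
  space is hemispherically registered; real anatomy is not perfectly
  mirror-symmetric, which is why the GM-snap option exists.
* The AI detection limit is governed by PET noise: at SNR 20 a 10% SUV
  reduction sits near the df-scaled threshold, and recovery of such faint
  lesions is unreliable at the voxel level (by design of the significance
  construction, not an implementation limit).
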