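# petdti

PET-guided diffusion tractography for the presurgical work-up of
medically refractory focal epilepsy. When structural MRI is negative,
interictal FDG-PET can still reveal the epileptic focus as a region of
glucose hypometabolism relative to the homologous contralateral cortex.
`petdti` implements that detection and couples it to diffusion-tensor
tractography of the surrounding white matter (WM), for imaging scientists
who want a reproducible, scriptable version of the workflow and a
ground-truth phantom to validate it on.

## What it computes

**Asymmetry mapping.** From a spatially normalized PET activity volume:

- SUV = C_PET × BW / Dose, smoothed (FWHM 2 mm), restricted to voxels with
  ≥ 30% gray matter, and scaled by the mean cerebellar GM SUV (SUVr);
- the voxel-wise asymmetry index against the sagittal reflection fI of the
  SUVr image I,

  AI = (I − fI) / (2 (I + fI)) × 100;

- its Z-score over GM, Z_AI = (AI − μ) / σ, thresholded at the lower-tail
  Student-t critical value with df = n − 1 (for n = 14 subjects, df = 13,
  Z_AI < −1.77);
- the largest focal suprathreshold GM cluster = the hypometabolic PET ROI
  (suspected epileptic focus), with a cluster-extent floor for type-I
  control.

**PET-guided tractography.** A 3×3×3 mm³ VOI at the ROI's WM-facing edge is
dilated 3, 9 and 15 mm into WM (and mirrored contralaterally); each region
seeds deterministic principal-eigenvector streamline tracking on a tensor
field fit by nonlinear least squares; each bundle is quantified by fiber
count, mean length, length-weighted mean FA, and mean cross-section; and
ipsilateral/contralateral ratios are compared across distances with an
exact Wilcoxon signed-rank test. Ratios below 1 indicate an ipsilateral WM
deficit; in epilepsy these are expected to be most pronounced at 3 mm from
the focus.

**Digital phantom.** `generate_phantom()` builds a mirror-symmetric
head-like dataset (PET + tissue maps + DWI synthesized from a ground-truth
tensor field with two mirror bundles, one degraded near the lesion) so the
whole chain is testable without patient data; `generate_cohort()` jitters
it into a synthetic patient cohort.

## Worked example

```r
library(petdti)

ph  <- generate_phantom(phantom_spec(rng_seed = 7))      # 15% lesion, left
res <- run_subject(ph, default_config(rng_seed = 7))

res$roi
#> <pet_roi> 171 voxels, left hemisphere, mean Z_AI -2.83, centroid (-43.1, -0.6, 0.3) mm

print(build_report(res$metrics))
#> <asymmetry_report>
#> Mean ipsilateral/contralateral ratios by distance:
#>  distance fiber_count mean_length mean_fa mean_cs
#>         3       0.607       0.612   0.888    1.21
#>         9       0.835       0.648   0.936    1.52
#>        15       0.900       0.716   0.953    1.37
```

The focus is recovered in the correct hemisphere at the injected lesion
site, and the ipsilateral deficit (ratios < 1 for count, length, FA) is
strongest at 3 mm, the distance adjacent to the focus. A file-based run
with NIfTI outputs, seed masks, per-bundle track dumps and an MD5
reproducibility manifest is available through `run_pipeline()`, and
`plot_report()` draws the normalized metrics by distance.

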