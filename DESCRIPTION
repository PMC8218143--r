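Package: petdti
Title: PET-Guided Diffusion Tractography for Epileptic Focus Assessment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for combining interictal FDG-PET asymmetry mapping with
    diffusion-tensor tractography in the presurgical work-up of refractory
    focal epilepsy. The package computes standardized uptake value (SUV) and
    cerebellum-normalized SUVr maps, voxel-wise hemispheric asymmetry-index
    (AI) and Z-score maps with a Student-t significance threshold, and
    extracts the largest focal hypometabolic gray-matter cluster as the
    suspected epileptic focus. White-matter seed regions are grown at graded
    distances (3, 9, 15 mm) around the focus and its mirrored contralateral
    homologue, deterministic streamline tractography is run on a fitted
    diffusion-tensor field, and ipsilateral/contralateral fiber-bundle
    asymmetry (count, length, weighted FA, cross-section) is quantified with
    exact Wilcoxon signed-rank comparisons across distances. A ground-truth
    digital head phantom (symmetric PET + two-bundle DWI) makes every stage
    testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    jsonlite,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
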