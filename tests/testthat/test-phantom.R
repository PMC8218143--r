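# mid-size phantom: large enough to hold bundles, fast enough for unit tests
mid_spec <- function(...) {
  phantom_spec(grid_shape = c(32, 32, 24), spacing = 2, n_directions = 12, ...)
}

test_that("phantom generation is deterministic under a fixed seed", {
  a <- generate_phantom(tiny_spec(rng_seed = 5), modalities = "pet")
  b <- generate_phantom(tiny_spec(rng_seed = 5), modalities = "pet")
  expect_identical(a$pet_activity$data, b$pet_activity$data)
  c <- generate_phantom(tiny_spec(rng_seed = 6), modalities = "pet")
  expect_false(identical(a$pet_activity$data, c$pet_activity$data))
})

test_that("pre-degradation structures are exact sagittal mirror images", {
  ph <- generate_phantom(mid_spec(hypometabolism_fraction = 0,
                                  fa_deficit_fraction = 0,
                                  dispersion_sd_deg = 0,
                                  pet_noise_sd = 0, dwi_snr = Inf))
  for (v in list(ph$gm_prob, ph$wm_prob, ph$csf_prob, ph$pet_activity)) {
    expect_equal(flip_sagittal(v)$data, v$data, tolerance = 1e-12)
  }
  expect_identical(ph$cerebellum_mask[dim(ph$cerebellum_mask)[1]:1, , ],
                   ph$cerebellum_mask)
  # bundle masks mirror each other; FA of the truth field is flip-invariant
  d1 <- dim(ph$truth$bundle_mask_ipsi)[1]
  expect_identical(ph$truth$bundle_mask_ipsi[d1:1, , ],
                   ph$truth$bundle_mask_contra)
  fa <- ph$truth$fa_true
  expect_equal(flip_sagittal(fa)$data, fa$data, tolerance = 1e-9)
})

test_that("lesion contrast propagates through the asymmetry equation", {
  # 20% hypometabolism, no noise, no smoothing: AI at the lesion centre is
  # (0.8 - 1) / (2 (0.8 + 1)) * 100 = -5.56%
  ph <- generate_phantom(tiny_spec(hypometabolism_fraction = 0.2,
                                   pet_noise_sd = 0), modalities = "pet")
  cfg <- default_config()
  cfg$suv$smoothing_fwhm <- 0
  res <- ai_map_stage(ph$pet_activity, ph$gm_prob, ph$cerebellum_mask, cfg)
  # a GM voxel inside the lesion (the exact centre rounds into WM on this
  # coarse fixture grid)
  centre_ijk <- round(world_to_voxel(res$ai, matrix(c(-11, -1, -1), 1)))
  expect_true(ph$truth$lesion_mask[centre_ijk[1], centre_ijk[2], centre_ijk[3]])
  ai_c <- res$ai$data[centre_ijk[1], centre_ijk[2], centre_ijk[3]]
  expect_equal(ai_c, (0.8 - 1) / (2 * (0.8 + 1)) * 100, tolerance = 1e-9)
  expect_equal(round(ai_c, 2), -5.56)
})

test_that("null phantom runs end to end with no detected focus", {
  ph <- generate_phantom(tiny_spec(hypometabolism_fraction = 0,
                                   pet_noise_sd = 0), modalities = "pet")
  res <- ai_map_stage(ph$pet_activity, ph$gm_prob, ph$cerebellum_mask)
  expect_equal(max(abs(res$ai$data), na.rm = TRUE), 0, tolerance = 1e-10)
  expect_false(res$roi$found)
  expect_match(res$status, "no significant hypometabolism")
})

test_that("degraded-bundle ground-truth FA matches the analytic shrunk triples", {
  f <- 0.2
  ph <- generate_phantom(mid_spec(fa_deficit_fraction = f,
                                  dispersion_sd_deg = 0, dwi_snr = Inf))
  tf <- ph$truth$tensor_field
  fa0 <- fa_from_eigenvalues(c(1.7, 0.3, 0.3) * 1e-3)
  idx <- which(ph$truth$bundle_mask_ipsi)
  w <- ph$truth$degradation_weight$data[idx]
  fa_vals <- ph$truth$fa_true$data[idx]
  expect_equal(fa_vals, (1 - w * f) * fa0, tolerance = 2e-3)
  # contralateral bundle keeps the healthy FA everywhere
  idx_c <- which(ph$truth$bundle_mask_contra)
  expect_equal(range(ph$truth$fa_true$data[idx_c]), c(fa0, fa0),
               tolerance = 1e-6)
  # eigenvalue clamping never fires on the noise-free truth field
  expect_equal(tf$n_negative_evals, 0L)
})

test_that("DWI signals follow the tensor model and carry Rician noise at the set SNR", {
  ph <- generate_phantom(mid_spec(dwi_snr = Inf, dispersion_sd_deg = 0))
  # noise-free: fitted tensors reproduce the truth FA in the bundles
  fit <- fit_tensor(ph$dwi, mask = ph$truth$bundle_mask_contra,
                    method = "linear_ls")
  fa_fit <- compute_fa(fit)
  idx <- which(ph$truth$bundle_mask_contra)
  expect_equal(fa_fit$data[idx], ph$truth$fa_true$data[idx], tolerance = 1e-6)
  # noisy: background b0 standard deviation matches s0 / snr within 15%
  ph2 <- generate_phantom(mid_spec(dwi_snr = 25))
  wm <- ph2$wm_prob$data >= 0.9 & !(ph2$truth$bundle_mask_ipsi |
                                      ph2$truth$bundle_mask_contra)
  b0 <- ph2$dwi$data[, , , 1][wm]
  expect_equal(sd(b0), 1000 / 25, tolerance = 0.15)
})

test_that("specs reject lesions touching the midline and bad fractions", {
  expect_error(phantom_spec(lesion_center = c(-3, 0, 0), lesion_radius = 5),
               "midline")
  expect_error(phantom_spec(hypometabolism_fraction = 1.2), "fractions")
  expect_error(phantom_spec(fa_deficit_fraction = -0.1), "fractions")
})

test_that("cohorts are reproducible, jittered, and manifest-consistent", {
  co <- generate_cohort(4, tiny_spec(), rng_seed = 11)
  co2 <- generate_cohort(4, tiny_spec(), rng_seed = 11)
  expect_identical(co$manifest, co2$manifest)
  expect_equal(nrow(co$manifest), 4)
  expect_equal(length(unique(co$manifest$rng_seed)), 4)
  # zero jitter: subjects identical up to their noise stream
  co0 <- generate_cohort(3, tiny_spec(),
                         jitter = list(center_mm = 0, hypometabolism = 0,
                                       fa_deficit = 0), rng_seed = 12)
  expect_equal(length(unique(co0$manifest$hypometabolism_fraction)), 1)
  expect_equal(length(unique(co0$manifest$lesion_y)), 1)
  # manifest matches the specs it describes
  expect_equal(co$manifest$hypometabolism_fraction,
               vapply(co$specs, function(s) s$hypometabolism_fraction, 0))
})

test_that("phantoms write a complete on-disk bundle", {
  ph <- generate_phantom(tiny_spec(), modalities = c("pet", "dwi"))
  dir <- tempfile()
  write_phantom(ph, dir)
  expect_true(all(file.exists(file.path(dir, c(
    "pet_activity.nii.gz", "gm_prob.nii.gz", "wm_prob.nii.gz",
    "csf_prob.nii.gz", "cerebellum_mask.nii.gz", "truth_lesion_mask.nii.gz",
    "dwi.nii.gz", "dwi.bval", "dwi.bvec", "phantom.json")))))
  back <- read_volume(file.path(dir, "gm_prob.nii.gz"))
  expect_equal(back$data, ph$gm_prob$data, tolerance = 1e-7)
  gt <- gradient_table(file.path(dir, "dwi.bval"), file.path(dir, "dwi.bvec"))
  expect_equal(gt$bvals, ph$gtab$bvals)
})
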