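#' Digital head phantom specification
#'
#' Describes a mirror-symmetric head-like layout (CSF shell, gray-matter
#' ribbon, white-matter core, cerebellar region) on a grid whose sagittal
#' midplane is exactly grid-aligned, with one focal GM hypometabolic lesion
#' and two mirror-image WM fiber bundles of which the ipsilateral one is
#' degraded in FA and orientation coherence around the lesion. The geometry
#' scales with the grid so miniature fixtures behave like the full phantom.
#'
#' Defaults emulate a template-space acquisition: a 64 x 64 x 48 grid at 2 mm
#' isotropic, b = 0 plus 64 diffusion directions at b = 1000 s/mm^2, healthy
#' bundle eigenvalues (1.7, 0.3, 0.3) x 10^-3 mm^2/s, PET noise at 5% of the
#' GM mean (SNR 20) and Rician DWI noise at SNR 30.
#'
#' @param grid_shape voxel dimensions, length 3.
#' @param spacing voxel size, mm (isotropic scalar or length 3).
#' @param lesion_center world-mm lesion centre; must keep the lesion sphere
#'   strictly within one hemisphere. Default: mid-GM on the left (-x) side.
#' @param lesion_radius lesion sphere radius, mm.
#' @param hypometabolism_fraction fractional SUV reduction inside the lesion
#'   (0.15 = 15%), in `[0, 1)`.
#' @param fa_deficit_fraction maximal fractional FA reduction of the
#'   ipsilateral bundle (applied with a spatial weight decaying from the
#'   lesion centre), in `[0, 1)`.
#' @param dispersion_sd_deg maximal additional angular dispersion (degrees)
#'   of the degraded bundle's fiber orientations, applied with the same
#'   weight.
#' @param baseline_dispersion_sd_deg angular dispersion present in both
#'   bundles (healthy WM is never perfectly coherent); built from a
#'   mirror-symmetric random field so the healthy bundles remain exact
#'   mirror images.
#' @param degradation_extent distance (mm) from the lesion centre at which
#'   bundle degradation has decayed to zero.
#' @param bundle_geometry `"straight"` (tubes along y) or `"arc"`
#'   (semicircular tubes).
#' @param pet_noise_sd Gaussian PET noise, as a fraction of the GM baseline.
#' @param dwi_snr Rician signal-to-noise ratio of the b = 0 signal; `Inf`
#'   disables DWI noise.
#' @param n_directions number of diffusion-encoding directions.
#' @param bvalue diffusion weighting, s/mm^2.
#' @param lambda_healthy healthy bundle eigenvalues, mm^2/s.
#' @param rng_seed integer seed; all phantom randomness derives from it.
#' @return list of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(64, 64, 48), spacing = 2,
                         lesion_center = NULL, lesion_radius = NULL,
                         hypometabolism_fraction = 0.15,
                         fa_deficit_fraction = 0.2,
                         dispersion_sd_deg = 20,
                         baseline_dispersion_sd_deg = 8,
                         degradation_extent = 25,
                         bundle_geometry = c("straight", "arc"),
                         pet_noise_sd = 0.05, dwi_snr = 30,
                         n_directions = 64, bvalue = 1000,
                         lambda_healthy = c(1.7, 0.3, 0.3) * 1e-3,
                         rng_seed = 1L) {
  bundle_geometry <- match.arg(bundle_geometry)
  grid_shape <- as.integer(grid_shape)
  spacing <- rep(as.numeric(spacing), length.out = 3)
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 8L), all(spacing > 0))
  half <- grid_shape * spacing / 2
  radii <- 0.78 * half
  if (is.null(lesion_radius)) lesion_radius <- 0.24 * radii[1]
  if (is.null(lesion_center)) lesion_center <- c(-0.84 * radii[1], 0, 0)
  for (f in c(hypometabolism_fraction, fa_deficit_fraction))
    if (!is.finite(f) || f < 0 || f >= 1)
      stop("fractions must lie in [0, 1)")
  if (abs(lesion_center[1]) < lesion_radius)
    stop("lesion sphere crosses the sagittal midline; it must sit strictly ",
         "within one hemisphere")
  if (!is.finite(pet_noise_sd) || pet_noise_sd < 0)
    stop("`pet_noise_sd` must be >= 0")
  if (n_directions < 6) stop("need >= 6 diffusion directions")
  structure(list(grid_shape = grid_shape, spacing = spacing, radii = radii,
                 lesion_center = as.numeric(lesion_center),
                 lesion_radius = lesion_radius,
                 hypometabolism_fraction = hypometabolism_fraction,
                 fa_deficit_fraction = fa_deficit_fraction,
                 dispersion_sd_deg = dispersion_sd_deg,
                 baseline_dispersion_sd_deg = baseline_dispersion_sd_deg,
                 degradation_extent = degradation_extent,
                 bundle_geometry = bundle_geometry,
                 pet_noise_sd = pet_noise_sd, dwi_snr = dwi_snr,
                 n_directions = as.integer(n_directions), bvalue = bvalue,
                 lambda_healthy = lambda_healthy,
                 rng_seed = as.integer(rng_seed)),
            class = "phantom_spec")
}

# Mirror-symmetric Gaussian 3-vector field: reflecting the grid about its
# central sagittal plane maps the field onto itself (with the x-component
# negated, as a vector field must). Draws from the current RNG stream.
sym_rand_field <- function(d) {
  nv <- prod(d)
  ru <- array(stats::rnorm(3 * nv), c(d, 3))
  half <- seq_len(d[1] %/% 2)
  mirr <- d[1] + 1 - half
  ru[mirr, , , 1] <- -ru[half, , , 1]
  ru[mirr, , , 2] <- ru[half, , , 2]
  ru[mirr, , , 3] <- ru[half, , , 3]
  if (d[1] %% 2 == 1) ru[d[1] %/% 2 + 1, , , 1] <- 0
  matrix(ru, nv, 3)
}

# Deterministic, well-spread unit directions (spherical Fibonacci lattice).
fibonacci_directions <- function(n) {
  i <- seq_len(n) - 1
  z <- (2 * i + 1) / n - 1
  phi <- i * pi * (3 - sqrt(5))
  r <- sqrt(pmax(1 - z^2, 0))
  cbind(r * cos(phi), r * sin(phi), z)
}

# FA of a prolate (a, b, b) triple after shrinking the anisotropy by factor
# (1 - t), trace preserved; returns the t that achieves `target_fa`.
shrink_for_target_fa <- function(a, b, target_fa) {
  lbar <- (a + 2 * b) / 3
  fa_of <- function(t) {
    d <- (a - b) * (1 - t)
    aa <- lbar + 2 * d / 3
    bb <- lbar - d / 3
    d / sqrt(aa^2 + 2 * bb^2)
  }
  grid <- seq(0, 1, length.out = 513)
  vals <- vapply(grid, fa_of, 0)
  stats::approx(vals, grid, xout = target_fa, rule = 2)$y
}

# Tube membership, surrounding WM sheath, and tangent field for the two
# mirror bundles. `pts` is an n x 3 world matrix; returns
# list(inside, sheath, tangent) for the bundle on the given side (sign of
# x). The sheath is a gyrus-like WM bulge with a uniform 0.06*rx margin
# around the tube, so healthy fibers have the same length wherever in the
# tube they are seeded.
bundle_field <- function(pts, side_sign, spec) {
  rx <- spec$radii[1]
  tube_r <- 0.12 * rx
  margin <- 0.08 * rx
  if (spec$bundle_geometry == "straight") {
    cx <- side_sign * 0.66 * rx
    y_ext <- 0.48 * rx
    ax_d <- sqrt((pts[, 1] - cx)^2 + pts[, 3]^2)
    inside <- ax_d <= tube_r & abs(pts[, 2]) <= y_ext
    sheath <- ax_d <= tube_r + margin & abs(pts[, 2]) <= y_ext + margin
    tangent <- matrix(rep(c(0, 1, 0), each = nrow(pts)), ncol = 3)
  } else {
    cc <- c(side_sign * 0.2 * rx, 0, 0)   # arc centre on the midline side
    R <- 0.42 * rx
    rad <- sqrt((pts[, 1] - cc[1])^2 + pts[, 2]^2)
    ax_d <- sqrt((rad - R)^2 + pts[, 3]^2)
    half <- side_sign * (pts[, 1] - cc[1]) >= 0
    inside <- ax_d <= tube_r & half
    sheath <- ax_d <= tube_r + margin &
      side_sign * (pts[, 1] - cc[1]) >= -margin
    tx <- -pts[, 2]
    ty <- pts[, 1] - cc[1]
    nrm <- sqrt(tx^2 + ty^2)
    nrm[nrm == 0] <- 1
    tangent <- cbind(tx / nrm, ty / nrm, 0)
  }
  list(inside = inside, sheath = sheath, tangent = tangent)
}

#' Generate a ground-truth digital phantom
#'
#' Builds the symmetric tissue layout, PET activity with a focal
#' hypometabolic lesion, and a DWI dataset synthesized from the ground-truth
#' tensor field. Pre-degradation, pre-noise structures are exactly invariant
#' under [flip_sagittal()]; the same `rng_seed` reproduces the output
#' bit-for-bit.
#'
#' @param spec a [phantom_spec()].
#' @param modalities which blocks to generate: subset of `c("pet", "dwi")`.
#'   Omitting `"dwi"` skips tensor/DWI synthesis (much faster when only the
#'   asymmetry-mapping stages are exercised).
#' @return list of class `phantom`: `pet_activity`, `gm_prob`, `wm_prob`,
#'   `csf_prob` (`volume3d`), `cerebellum_mask`, `brain_mask` (logical), and
#'   with `"dwi"`: `dwi` ([dwi_dataset()]), `gtab`. `truth` carries
#'   `lesion_mask`, per-side bundle masks, the ground-truth `tensor_field`,
#'   `fa_true` and the degradation-weight volume.
#' @export
generate_phantom <- function(spec = phantom_spec(),
                             modalities = c("pet", "dwi")) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$grid_shape
  geo <- volume3d(array(0, d), spec$spacing)
  grid <- as.matrix(expand.grid(i = seq_len(d[1]), j = seq_len(d[2]),
                                k = seq_len(d[3])))
  W <- voxel_to_world(geo, grid)
  rho <- sqrt((W[, 1] / spec$radii[1])^2 + (W[, 2] / spec$radii[2])^2 +
                (W[, 3] / spec$radii[3])^2)
  soft <- 0.015
  trans <- function(r) stats::plogis((r - rho) / soft)
  # WM = ellipsoidal core plus the gyrus-like sheaths embedding the bundles
  side_ipsi <- if (spec$lesion_center[1] < 0) -1 else 1
  bi <- bundle_field(W, side_ipsi, spec)
  bc <- bundle_field(W, -side_ipsi, spec)
  wm_p <- pmax(trans(0.75), as.numeric(bi$sheath | bc$sheath) * trans(0.90))
  gm_p <- pmax(trans(0.92) - wm_p, 0)
  csf_p <- trans(1.0) - trans(0.92)
  mk <- function(v) volume3d(array(v, d), spec$spacing, geo$affine)
  gm_prob <- mk(gm_p); wm_prob <- mk(wm_p); csf_prob <- mk(csf_p)
  brain_mask <- array(trans(1.0) > 0.5, d)
  cereb <- array(gm_p >= 0.5 & W[, 3] < -0.68 * spec$radii[3], d)

  lesion_d <- sqrt((W[, 1] - spec$lesion_center[1])^2 +
                     (W[, 2] - spec$lesion_center[2])^2 +
                     (W[, 3] - spec$lesion_center[3])^2)
  in_lesion <- lesion_d <= spec$lesion_radius
  lesion_mask <- array(in_lesion & gm_p >= 0.30, d)

  # PET: GM-weighted baseline, multiplicative lesion, Gaussian noise
  a0 <- 8000                       # Bq/mL at the GM peak
  act <- a0 * (gm_p + 0.25 * wm_p + 0.05 * csf_p)
  act[in_lesion] <- act[in_lesion] * (1 - spec$hypometabolism_fraction)
  out <- list(spec = spec, gm_prob = gm_prob, wm_prob = wm_prob,
              csf_prob = csf_prob, cerebellum_mask = cereb,
              brain_mask = brain_mask)
  truth <- list(lesion_mask = lesion_mask)

  withr::with_seed(spec$rng_seed, {
    if ("pet" %in% modalities) {
      if (spec$pet_noise_sd > 0)
        act <- act + stats::rnorm(length(act), sd = spec$pet_noise_sd * a0)
      out$pet_activity <- mk(act)
    }
    if ("dwi" %in% modalities) {
      wm_hard <- wm_p >= 0.5
      in_bi <- bi$inside & wm_hard
      in_bc <- bc$inside & wm_hard
      lam <- spec$lambda_healthy
      fa0 <- fa_from_eigenvalues(lam)

      # per-voxel eigenvalue triples and principal directions
      nv <- nrow(W)
      l1 <- numeric(nv); l23 <- numeric(nv)
      e1 <- matrix(0, nv, 3)
      is_wm <- wm_p >= pmax(gm_p, csf_p) & as.vector(brain_mask)
      tissue_iso <- ifelse(is_wm, 0.7e-3,
                           ifelse(gm_p >= csf_p, 0.8e-3, 3.0e-3))
      in_brain <- as.vector(brain_mask)
      l1[in_brain] <- tissue_iso[in_brain]
      l23[in_brain] <- tissue_iso[in_brain]
      e1[in_brain, 1] <- 1          # arbitrary axis for isotropic voxels
      # background WM outside the bundles: moderate anisotropy (FA 0.25,
      # MD 0.7e-3) with incoherent, mirror-symmetric orientations -- real
      # deep WM is never isotropic, and the incoherence stops tracking via
      # the angle criterion rather than the FA floor
      bg_wm <- is_wm & !(bi$sheath | bc$sheath)
      if (any(bg_wm)) {
        rv <- sym_rand_field(d)
        nrm <- sqrt(rowSums(rv^2)); nrm[nrm == 0] <- 1
        l1[bg_wm] <- 0.9064e-3
        l23[bg_wm] <- 0.5968e-3
        e1[bg_wm, ] <- (rv / nrm)[bg_wm, , drop = FALSE]
      }
      # shared baseline orientation dispersion (mirror-symmetric field, so
      # the healthy bundles remain exact mirror images of each other)
      base_jit <- if (spec$baseline_dispersion_sd_deg > 0)
        sym_rand_field(d) * tan(spec$baseline_dispersion_sd_deg * pi / 180)
      else NULL

      # bundle core plus its coherent low-FA fringe (superficial WM): the
      # fringe shares the core's tangent field but has FA 0.45 at the same
      # mean diffusivity, like the partial-volume rim of a real tract
      lam_fringe <- c(1.091, 0.504, 0.504) * 1e-3
      wgt <- pmax(0, 1 - lesion_d / spec$degradation_extent)
      for (side in c("ipsi", "contra")) {
        bf <- if (side == "ipsi") bi else bc
        for (part in c("core", "fringe")) {
          sel <- if (part == "core") bf$inside & wm_hard
                 else bf$sheath & !bf$inside & wm_hard
          if (!any(sel)) next
          tg <- bf$tangent[sel, , drop = FALSE]
          lp <- if (part == "core") lam else lam_fringe
          fa_part <- fa_from_eigenvalues(lp)
          a <- rep(lp[1], sum(sel)); b <- rep(lp[2], sum(sel))
          if (side == "ipsi" && spec$fa_deficit_fraction > 0) {
            target <- (1 - wgt[sel] * spec$fa_deficit_fraction) * fa_part
            t_shrink <- shrink_for_target_fa(lp[1], lp[2], target)
            delta <- (lp[1] - lp[2]) * (1 - t_shrink)
            lbar <- (lp[1] + 2 * lp[2]) / 3
            a <- lbar + 2 * delta / 3
            b <- lbar - delta / 3
          }
          if (!is.null(base_jit))
            tg <- tg + base_jit[sel, , drop = FALSE]
          if (side == "ipsi" && spec$dispersion_sd_deg > 0) {
            sd_tan <- tan(pmin(wgt[sel] * spec$dispersion_sd_deg, 80) * pi / 180)
            tg <- tg + matrix(stats::rnorm(length(tg)), ncol = 3) * sd_tan
          }
          tg <- tg / sqrt(rowSums(tg^2))
          l1[sel] <- a; l23[sel] <- b
          e1[sel, ] <- tg
        }
      }

      # assemble lower-triangular tensors D = l23 I + (l1 - l23) e1 e1'
      lower <- array(0, c(d, 6))
      comp <- function(v) array(v, d)
      dl <- l1 - l23
      lower[, , , 1] <- comp(l23 + dl * e1[, 1]^2)
      lower[, , , 2] <- comp(l23 + dl * e1[, 2]^2)
      lower[, , , 3] <- comp(l23 + dl * e1[, 3]^2)
      lower[, , , 4] <- comp(dl * e1[, 1] * e1[, 2])
      lower[, , , 5] <- comp(dl * e1[, 1] * e1[, 3])
      lower[, , , 6] <- comp(dl * e1[, 2] * e1[, 3])
      tf_true <- tensor_field(lower, brain_mask, spacing = spec$spacing,
                              affine = geo$affine)

      dirs <- fibonacci_directions(spec$n_directions)
      bvals <- c(0, rep(spec$bvalue, spec$n_directions))
      bvecs <- rbind(c(0, 0, 0), dirs)
      gtab <- gradient_table(bvals, bvecs)
      s0 <- 1000
      nvol <- gtab$n
      sig <- matrix(0, nv, nvol)
      s0_vox <- ifelse(in_brain, s0, 0)
      sig[, 1] <- s0_vox
      for (j in seq_len(spec$n_directions)) {
        g <- dirs[j, ]
        q <- dl * (e1[, 1] * g[1] + e1[, 2] * g[2] + e1[, 3] * g[3])^2 + l23
        sig[, j + 1] <- s0_vox * exp(-spec$bvalue * q)
      }
      if (is.finite(spec$dwi_snr) && spec$dwi_snr > 0) {
        ns <- s0 / spec$dwi_snr
        n1 <- matrix(stats::rnorm(length(sig), sd = ns), nrow = nv)
        n2 <- matrix(stats::rnorm(length(sig), sd = ns), nrow = nv)
        sig <- sqrt((sig + n1)^2 + n2^2)
        sig[!in_brain, ] <- 0
      }
      out$gtab <- gtab
      out$dwi <- dwi_dataset(array(sig, c(d, nvol)), gtab, spec$spacing,
                             geo$affine)
      truth$bundle_mask_ipsi <- array(in_bi, d)
      truth$bundle_mask_contra <- array(in_bc, d)
      truth$tensor_field <- tf_true
      truth$fa_true <- compute_fa(tf_true)
      truth$degradation_weight <- mk(wgt)
    }
  })
  out$truth <- truth
  class(out) <- "phantom"
  out
}

#' @export
print.phantom <- function(x, ...) {
  d <- x$spec$grid_shape
  cat(sprintf("<phantom> %d x %d x %d @ %s mm, lesion %.0f%% at (%.0f, %.0f, %.0f) mm\n",
              d[1], d[2], d[3], paste(x$spec$spacing, collapse = "x"),
              100 * x$spec$hypometabolism_fraction,
              x$spec$lesion_center[1], x$spec$lesion_center[2],
              x$spec$lesion_center[3]))
  cat(sprintf("  modalities: %s\n",
              paste(intersect(c("pet_activity", "dwi"), names(x)),
                    collapse = ", ")))
  invisible(x)
}

#' Generate a cohort of jittered phantom subjects
#'
#' Draws `n_subjects` variations of a template spec with jittered lesion
#' position and degradation magnitudes, standing in for a patient cohort.
#' Each subject gets a deterministic derived seed, so the cohort is fully
#' reproducible. By default only the per-subject specs plus a ground-truth
#' manifest are returned (a materialized full-size subject is ~100 MB);
#' `materialize = TRUE` additionally generates the phantom objects.
#'
#' @param n_subjects number of subjects (>= 1).
#' @param template a [phantom_spec()] used as the base.
#' @param jitter list with elements `center_mm` (max |uniform| shift of the
#'   lesion centre in y/z), `hypometabolism` and `fa_deficit` (max |uniform|
#'   shifts of the fractions).
#' @param rng_seed cohort-level seed.
#' @param materialize if `TRUE`, return generated phantoms too.
#' @return list of class `phantom_cohort`: `specs` (list of `phantom_spec`),
#'   `manifest` (data.frame of per-subject ground truth), and optionally
#'   `phantoms`.
#' @export
generate_cohort <- function(n_subjects, template = phantom_spec(),
                            jitter = list(center_mm = 4, hypometabolism = 0.03,
                                          fa_deficit = 0.05),
                            rng_seed = 100L, materialize = FALSE) {
  stopifnot(n_subjects >= 1)
  jit <- utils::modifyList(list(center_mm = 4, hypometabolism = 0.03,
                                fa_deficit = 0.05), as.list(jitter))
  specs <- withr::with_seed(rng_seed, {
    lapply(seq_len(n_subjects), function(i) {
      sp <- template
      sp$lesion_center[2:3] <- sp$lesion_center[2:3] +
        stats::runif(2, -jit$center_mm, jit$center_mm)
      sp$hypometabolism_fraction <- min(0.95, max(0.01,
        sp$hypometabolism_fraction + stats::runif(1, -jit$hypometabolism,
                                                  jit$hypometabolism)))
      sp$fa_deficit_fraction <- min(0.95, max(0,
        sp$fa_deficit_fraction + stats::runif(1, -jit$fa_deficit,
                                              jit$fa_deficit)))
      sp$rng_seed <- as.integer((rng_seed + 7919L * i) %% .Machine$integer.max)
      sp
    })
  })
  manifest <- do.call(rbind, lapply(seq_along(specs), function(i) {
    sp <- specs[[i]]
    data.frame(subject = i,
               lesion_x = sp$lesion_center[1], lesion_y = sp$lesion_center[2],
               lesion_z = sp$lesion_center[3], lesion_radius = sp$lesion_radius,
               hypometabolism_fraction = sp$hypometabolism_fraction,
               fa_deficit_fraction = sp$fa_deficit_fraction,
               rng_seed = sp$rng_seed)
  }))
  out <- list(specs = specs, manifest = manifest)
  if (materialize)
    out$phantoms <- lapply(specs, generate_phantom)
  class(out) <- "phantom_cohort"
  out
}

#' @export
print.phantom_cohort <- function(x, ...) {
  cat(sprintf("<phantom_cohort> %d subjects%s\n", length(x$specs),
              if (!is.null(x$phantoms)) " (materialized)" else ""))
  invisible(x)
}

#' Write a phantom to disk
#'
#' NIfTI volumes, FSL bval/bvec files, truth masks and a JSON manifest.
#'
#' @param phantom a `phantom`.
#' @param dir output directory.
#' @return the directory, invisibly.
#' @export
write_phantom <- function(phantom, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  g <- phantom$gm_prob
  if (!is.null(phantom$pet_activity))
    write_volume(phantom$pet_activity, file.path(dir, "pet_activity.nii.gz"))
  write_volume(phantom$gm_prob, file.path(dir, "gm_prob.nii.gz"))
  write_volume(phantom$wm_prob, file.path(dir, "wm_prob.nii.gz"))
  write_volume(phantom$csf_prob, file.path(dir, "csf_prob.nii.gz"))
  write_mask(volume3d(phantom$cerebellum_mask, g$spacing, g$affine),
             file.path(dir, "cerebellum_mask.nii.gz"))
  write_mask(volume3d(phantom$truth$lesion_mask, g$spacing, g$affine),
             file.path(dir, "truth_lesion_mask.nii.gz"))
  if (!is.null(phantom$dwi)) {
    img <- nifti_with_affine(phantom$dwi$data, phantom$dwi$affine,
                             phantom$dwi$spacing)
    RNifti::writeNifti(img, file.path(dir, "dwi.nii.gz"))
    write_gradient_table(phantom$gtab, file.path(dir, "dwi.bval"),
                         file.path(dir, "dwi.bvec"))
  }
  jsonlite::write_json(
    list(spec = unclass(phantom$spec)), file.path(dir, "phantom.json"),
    auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
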