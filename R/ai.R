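#' SUV calculation parameters
#'
#' @param body_weight patient body weight in grams.
#' @param injected_dose net injected tracer dose in Bq.
#' @param gm_fraction_threshold minimum gray-matter probability for a voxel to
#'   enter the asymmetry analysis (default 0.30, i.e. "at least 30% GM").
#' @param smoothing_fwhm Gaussian smoothing FWHM in mm applied to the SUV map
#'   (default 2).
#' @return list of class `suv_params`.
#' @export
suv_params <- function(body_weight, injected_dose,
                       gm_fraction_threshold = 0.30, smoothing_fwhm = 2) {
  if (!is.finite(body_weight) || body_weight <= 0)
    stop("`body_weight` must be > 0 g")
  if (!is.finite(injected_dose) || injected_dose <= 0)
    stop("`injected_dose` must be > 0 Bq")
  if (gm_fraction_threshold < 0 || gm_fraction_threshold > 1)
    stop("`gm_fraction_threshold` must lie in [0, 1]")
  if (smoothing_fwhm < 0) stop("`smoothing_fwhm` must be >= 0")
  structure(list(body_weight = body_weight, injected_dose = injected_dose,
                 gm_fraction_threshold = gm_fraction_threshold,
                 smoothing_fwhm = smoothing_fwhm),
            class = "suv_params")
}

#' Standardized uptake value map
#'
#' SUV = activity concentration x body weight / injected dose, voxel-wise.
#' With activity in Bq/mL, weight in g and dose in Bq the units cancel under
#' the usual 1 g/mL tissue-density convention, giving a unitless index.
#'
#' @param activity `volume3d` of activity concentration, Bq/mL.
#' @param params a [suv_params()] object.
#' @return `volume3d` of SUV.
#' @export
compute_suv <- function(activity, params) {
  stopifnot(is_volume3d(activity), inherits(params, "suv_params"))
  volume3d(activity$data * params$body_weight / params$injected_dose,
           activity$spacing, activity$affine)
}

#' Gray-matter analysis mask
#'
#' Voxels whose GM probability is at least `threshold` (inclusive boundary).
#'
#' @param gm_prob `volume3d` of gray-matter probability in `[0, 1]`.
#' @param threshold GM fraction cutoff in `[0, 1]`.
#' @return logical 3-D array sharing `gm_prob`'s grid.
#' @export
apply_gm_mask <- function(gm_prob, threshold = 0.30) {
  if (!is.finite(threshold) || threshold < 0 || threshold > 1)
    stop("`threshold` must lie in [0, 1]")
  m <- gm_prob$data >= threshold
  m[is.na(m)] <- FALSE
  m
}

#' Cerebellar normalization of SUV
#'
#' Divides the SUV map by the mean SUV over the cerebellar gray matter
#' (reference = `cerebellum_mask & gm_mask`), removing global-metabolism
#' differences. The mean SUVr over the reference region is 1 by construction.
#' Voxels outside the GM mask are set to `NA` (only GM enters the asymmetry
#' analysis).
#'
#' @param suv `volume3d` of (smoothed) SUV.
#' @param gm_mask logical array from [apply_gm_mask()].
#' @param cerebellum_mask logical array marking the cerebellum.
#' @return `volume3d` of relative SUV (SUVr), `NA` outside GM.
#' @export
normalize_cerebellum <- function(suv, gm_mask, cerebellum_mask) {
  ref <- gm_mask & cerebellum_mask
  if (!any(ref))
    stop("cerebellar reference region is empty (no voxel is both GM and cerebellum)")
  ref_mean <- mean(suv$data[ref], na.rm = TRUE)
  if (!is.finite(ref_mean) || ref_mean <= 0)
    stop("cerebellar reference mean is ", ref_mean, "; cannot normalize")
  out <- suv$data / ref_mean
  out[!gm_mask] <- NA_real_
  volume3d(out, suv$spacing, suv$affine)
}

#' Hemispheric asymmetry-index map
#'
#' AI = (I - fI) / (2 (I + fI)) x 100, where I is the SUVr image and fI its
#' sagittal reflection. AI is antisymmetric (AI at a voxel equals -AI at its
#' mirror, exactly so for a grid-aligned midline) and bounded in (-50, 50) for
#' positive images. Voxels where I or fI is undefined, or where I + fI = 0,
#' are `NA` and excluded from all statistics.
#'
#' @param suvr `volume3d` of relative SUV (NA outside the analysis mask).
#' @param midline_world_x sagittal midline, world mm.
#' @return `volume3d` of AI in percent.
#' @export
compute_ai <- function(suvr, midline_world_x = default_midline(suvr)) {
  fl <- flip_sagittal(suvr, midline_world_x)
  i <- suvr$data
  fi <- fl$data
  denom <- 2 * (i + fi)
  ai <- (i - fi) / denom * 100
  ai[!is.finite(ai)] <- NA_real_
  volume3d(ai, suvr$spacing, suvr$affine)
}

#' Z-scored asymmetry-index map
#'
#' Standardizes the AI map by the mean and standard deviation of AI over all
#' gray-matter voxels with a defined AI. The default standard deviation is the
#' population form (divide by N): the GM voxels are treated as the
#' distribution itself, not a sample from one.
#'
#' @param ai `volume3d` from [compute_ai()].
#' @param gm_mask logical GM analysis mask.
#' @param sd_type `"population"` (default) or `"sample"`.
#' @return `volume3d` of Z_AI, with attributes `mu` and `sigma`.
#' @export
compute_zai <- function(ai, gm_mask, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  vals <- ai$data[gm_mask]
  vals <- vals[!is.na(vals)]
  if (length(vals) < 2L)
    stop("need at least 2 GM voxels with a defined AI")
  mu <- mean(vals)
  sigma <- stats::sd(vals)
  if (sd_type == "population")
    sigma <- sigma * sqrt((length(vals) - 1) / length(vals))
  if (!is.finite(sigma) || sigma == 0)
    stop("AI standard deviation over GM is zero; Z_AI is undefined ",
         "(image is hemispherically symmetric)")
  z <- (ai$data - mu) / sigma
  out <- volume3d(z, ai$spacing, ai$affine)
  attr(out, "mu") <- mu
  attr(out, "sigma") <- sigma
  out
}

#' Significance threshold for the Z_AI map
#'
#' With n subjects the AI distribution is assessed against a Student-t
#' reference with df = n - 1 degrees of freedom (the Crawford-Garthwaite
#' single-case construction), so hypometabolism is declared where Z_AI falls
#' below the lower-tail t critical value at level `alpha`. For n = 14
#' (df = 13) and alpha = 0.05 this gives -1.77 (2 d.p.).
#'
#' @param n_subjects number of subjects in the sample (df = n - 1). Supply
#'   either this or `df`.
#' @param alpha one-sided significance level in (0, 0.5).
#' @param df degrees of freedom, overrides `n_subjects`.
#' @return list of class `ai_threshold` with `df`, `alpha`, `critical_z`
#'   (exact, negative) and `critical_z_2dp` (reporting value).
#' @export
ai_threshold <- function(n_subjects = NULL, alpha = 0.05, df = NULL) {
  if (is.null(df)) {
    if (is.null(n_subjects)) stop("supply `n_subjects` or `df`")
    df <- n_subjects - 1L
  }
  if (!is.finite(df) || df < 1) stop("`df` must be >= 1")
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 0.5)
    stop("`alpha` must lie in (0, 0.5)")
  cz <- stats::qt(alpha, df = df)
  structure(list(df = df, alpha = alpha, critical_z = cz,
                 critical_z_2dp = round(cz, 2)),
            class = "ai_threshold")
}

#' @export
print.ai_threshold <- function(x, ...) {
  cat(sprintf("<ai_threshold> df = %g, alpha = %g, Z_AI < %.2f\n",
              x$df, x$alpha, x$critical_z_2dp))
  invisible(x)
}

#' Extract the hypometabolic PET ROI (suspected epileptic focus)
#'
#' Thresholds the Z_AI map at `critical_z` within the GM mask and returns the
#' largest connected component as the ROI. "Focal" is operationalized as a
#' connected cluster of at least `min_voxels` voxels: under hemispherically
#' symmetric noise the voxel-wise threshold alone always leaves chance
#' suprathreshold clusters, and the extent floor is what keeps the detection
#' specific (see the methods vignette for its calibration).
#'
#' @param zai `volume3d` from [compute_zai()].
#' @param gm_mask logical GM analysis mask.
#' @param critical_z negative threshold (voxels with Z_AI strictly below it
#'   are suprathreshold).
#' @param connectivity cluster connectivity (default 26).
#' @param min_voxels minimum cluster extent, voxels, for a cluster to count
#'   as a focal ROI (default 40, about 0.32 mL at 2 mm isotropic).
#' @param midline_world_x midline used to lateralize the ROI.
#' @return list of class `pet_roi`: `found`, `status`, `mask`, `voxel_count`,
#'   `mean_zai`, `min_zai`, `hemisphere` (`"left"` if the centroid world-x is
#'   below the midline), `centroid_world`, `secondary_sizes` (other cluster
#'   sizes, for reporting).
#' @export
extract_roi <- function(zai, gm_mask, critical_z, connectivity = 26L,
                        min_voxels = 40L,
                        midline_world_x = default_midline(zai)) {
  if (!is.finite(critical_z) || critical_z >= 0)
    stop("`critical_z` must be negative")
  supra <- gm_mask & !is.na(zai$data) & zai$data < critical_z
  empty <- list(found = FALSE, status = "no significant hypometabolism",
                mask = supra & FALSE, voxel_count = 0L,
                mean_zai = NA_real_, min_zai = NA_real_,
                hemisphere = NA_character_,
                centroid_world = rep(NA_real_, 3), secondary_sizes = integer(0))
  class(empty) <- "pet_roi"
  if (!any(supra)) return(empty)
  cc <- connected_components(supra, connectivity)
  if (cc$sizes[1] < min_voxels) return(empty)
  roi_mask <- cc$labels == 1L
  ijk <- which(roi_mask, arr.ind = TRUE)
  w <- voxel_to_world(zai, ijk)
  centroid <- colMeans(w)
  res <- list(found = TRUE, status = "ok", mask = roi_mask,
              voxel_count = as.integer(cc$sizes[1]),
              mean_zai = mean(zai$data[roi_mask]),
              min_zai = min(zai$data[roi_mask]),
              hemisphere = if (centroid[1] < midline_world_x) "left" else "right",
              centroid_world = centroid,
              secondary_sizes = cc$sizes[-1][cc$sizes[-1] >= min_voxels])
  class(res) <- "pet_roi"
  res
}

#' @export
print.pet_roi <- function(x, ...) {
  if (!x$found) {
    cat("<pet_roi> ", x$status, "\n", sep = "")
  } else {
    cat(sprintf(
      "<pet_roi> %d voxels, %s hemisphere, mean Z_AI %.2f, centroid (%.1f, %.1f, %.1f) mm\n",
      x$voxel_count, x$hemisphere, x$mean_zai,
      x$centroid_world[1], x$centroid_world[2], x$centroid_world[3]))
  }
  invisible(x)
}

#' Dice overlap between two masks
#'
#' @param a,b logical arrays of identical shape.
#' @return 2|a&b| / (|a| + |b|), or `NA` if both are empty.
#' @export
dice_coefficient <- function(a, b) {
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(NA_real_)
  2 * sum(a & b) / (sa + sb)
}
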