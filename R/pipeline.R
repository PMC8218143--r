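# Pipeline orchestration: config handling, per-subject analysis, cohort
# runs, and a file-based front end with a reproducibility manifest.

#' Default pipeline configuration
#'
#' Nested list of every tunable the pipeline exposes, with the method's
#' defaults: SUV smoothing FWHM 2 mm, >= 30% GM analysis rule, cerebellar GM
#' reference, Student-t asymmetry threshold for n = 14 subjects at
#' alpha = 0.05, focal-cluster extent floor of 40 voxels, 3 x 3 x 3 mm^3 VOI
#' dilated to 3/9/15 mm into WM (p >= 0.5), nonlinear tensor fit over WM-ish
#' voxels, and deterministic Euler tracking (step 0.5 mm, 45 degrees, FA
#' stop 0.10, 8 seeds/voxel).
#'
#' @param rng_seed integer master seed for tracking jitter.
#' @return nested configuration list.
#' @export
default_config <- function(rng_seed = 1L) {
  list(
    suv = list(body_weight = 70000, injected_dose = 1.9e8,
               gm_fraction_threshold = 0.30, smoothing_fwhm = 2,
               smooth_before_mask = TRUE),
    ai = list(n_subjects = 14, alpha = 0.05, sd_type = "population",
              connectivity = 26, min_roi_voxels = 40),
    seeds = list(voi_edge = 3, distances = c(3, 9, 15), cumulative = TRUE,
                 wm_threshold = 0.5, snap_contralateral = FALSE),
    fit = list(method = "nonlinear_ls", mask_threshold = 0.25,
               upsample_to = NULL),
    tracking = list(step = 0.5, max_angle = 45, fa_stop = 0.10,
                    min_length = 10, max_length = 250, seeds_per_voxel = 8,
                    interp = "nearest", integrator = "euler"),
    rng_seed = as.integer(rng_seed))
}

merge_config <- function(defaults, user, path = "") {
  for (k in names(user)) {
    if (!k %in% names(defaults))
      stop("unknown configuration key: ", paste0(path, k))
    if (is.list(defaults[[k]]) && is.list(user[[k]])) {
      defaults[[k]] <- merge_config(defaults[[k]], user[[k]],
                                    paste0(path, k, "/"))
    } else {
      defaults[[k]] <- user[[k]]
    }
  }
  defaults
}

#' Validate and normalize a pipeline configuration
#'
#' Accepts a YAML file path or a nested list, fills in every default from
#' [default_config()], rejects unknown keys (reporting the offending key
#' path) and unit violations, and normalizes the seed distances to strictly
#' increasing order.
#'
#' @param config YAML path or list. `input` keys (`phantom` spec overrides or
#'   file `paths`) are carried through untouched.
#' @return normalized configuration list.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a YAML file path or a list")
  input <- config$input
  config$input <- NULL
  cfg <- merge_config(default_config(), config)
  cfg$input <- input
  if (cfg$suv$body_weight <= 0) stop("suv/body_weight must be > 0 g")
  if (cfg$suv$injected_dose <= 0) stop("suv/injected_dose must be > 0 Bq")
  if (cfg$suv$gm_fraction_threshold < 0 || cfg$suv$gm_fraction_threshold > 1)
    stop("suv/gm_fraction_threshold must lie in [0, 1]")
  if (cfg$suv$smoothing_fwhm < 0) stop("suv/smoothing_fwhm must be >= 0 mm")
  if (cfg$ai$n_subjects < 2) stop("ai/n_subjects must be >= 2")
  if (cfg$ai$alpha <= 0 || cfg$ai$alpha >= 0.5)
    stop("ai/alpha must lie in (0, 0.5)")
  if (!cfg$ai$connectivity %in% c(6, 18, 26))
    stop("ai/connectivity must be 6, 18 or 26")
  d <- sort(as.numeric(cfg$seeds$distances))
  if (any(d <= 0) || anyDuplicated(d)) stop("seeds/distances must be positive and distinct")
  cfg$seeds$distances <- d
  if (cfg$seeds$wm_threshold < 0 || cfg$seeds$wm_threshold > 1)
    stop("seeds/wm_threshold must lie in [0, 1]")
  if (!cfg$fit$method %in% c("nonlinear_ls", "linear_ls"))
    stop("fit/method must be nonlinear_ls or linear_ls")
  # tracking_params() performs its own checks
  do.call(tracking_params, c(cfg$tracking, list(rng_seed = cfg$rng_seed)))
  cfg
}

#' Asymmetry-mapping stage: PET activity to hypometabolic ROI
#'
#' Runs SUV -> smoothing -> GM mask -> cerebellar normalization -> AI ->
#' Z_AI -> focal-cluster extraction. A hemispherically symmetric image (zero
#' AI variance) or the absence of a sufficiently large suprathreshold
#' cluster ends cleanly with status `"no significant hypometabolism"`.
#'
#' @param activity PET activity `volume3d` (Bq/mL).
#' @param gm_prob GM probability `volume3d`.
#' @param cerebellum_mask logical cerebellum mask.
#' @param config list from [validate_config()] / [default_config()].
#' @return list with `suv`, `gm_mask`, `suvr`, `ai`, `zai`, `threshold`,
#'   `roi`, `status`.
#' @export
ai_map_stage <- function(activity, gm_prob, cerebellum_mask,
                         config = default_config()) {
  params <- suv_params(config$suv$body_weight, config$suv$injected_dose,
                       config$suv$gm_fraction_threshold,
                       config$suv$smoothing_fwhm)
  suv <- compute_suv(activity, params)
  if (config$suv$smooth_before_mask)
    suv <- gaussian_smooth(suv, params$smoothing_fwhm)
  gm_mask <- apply_gm_mask(gm_prob, params$gm_fraction_threshold)
  if (!config$suv$smooth_before_mask) {
    masked <- suv
    masked$data[!gm_mask] <- 0
    suv <- gaussian_smooth(masked, params$smoothing_fwhm)
  }
  suvr <- normalize_cerebellum(suv, gm_mask, cerebellum_mask)
  midline <- default_midline(suvr)
  ai <- compute_ai(suvr, midline)
  thr <- ai_threshold(n_subjects = config$ai$n_subjects,
                      alpha = config$ai$alpha)
  zai <- tryCatch(compute_zai(ai, gm_mask, config$ai$sd_type),
                  error = function(e) NULL)
  if (is.null(zai)) {
    roi <- structure(list(found = FALSE,
                          status = "no significant hypometabolism",
                          mask = array(FALSE, dim(ai$data)), voxel_count = 0L,
                          mean_zai = NA_real_, min_zai = NA_real_,
                          hemisphere = NA_character_,
                          centroid_world = rep(NA_real_, 3),
                          secondary_sizes = integer(0)),
                     class = "pet_roi")
  } else {
    roi <- extract_roi(zai, gm_mask, thr$critical_z,
                       connectivity = config$ai$connectivity,
                       min_voxels = config$ai$min_roi_voxels,
                       midline_world_x = midline)
  }
  list(suv = suv, gm_mask = gm_mask, suvr = suvr, ai = ai, zai = zai,
       threshold = thr, roi = roi, status = roi$status)
}

#' Tensor-fitting stage
#'
#' Fits the diffusion tensor over WM-weighted voxels (optionally after
#' upsampling the DWI) and derives the FA map used for tracking.
#'
#' @param dwi a [dwi_dataset()].
#' @param wm_prob WM probability `volume3d` on the DWI grid.
#' @param config pipeline configuration.
#' @return list with `tf` (tensor field) and `fa` (`volume3d`).
#' @export
dti_stage <- function(dwi, wm_prob, config = default_config()) {
  if (!is.null(config$fit$upsample_to)) {
    ts <- config$fit$upsample_to
    gt <- dwi$gtab
    vols <- lapply(seq_len(gt$n), function(j)
      resample(volume3d(dwi$data[, , , j], dwi$spacing, dwi$affine), ts))
    nd <- dim(vols[[1]]$data)
    arr <- array(0, c(nd, gt$n))
    for (j in seq_len(gt$n)) arr[, , , j] <- vols[[j]]$data
    arr[is.na(arr)] <- 0
    dwi <- dwi_dataset(arr, gt, vols[[1]]$spacing, vols[[1]]$affine)
    wm_prob <- resample(wm_prob, ts)
  }
  mask <- !is.na(wm_prob$data) & wm_prob$data >= config$fit$mask_threshold
  tf <- fit_tensor(dwi, mask = mask, method = config$fit$method)
  list(tf = tf, fa = compute_fa(tf))
}

#' Tracking and quantification stage
#'
#' Tracks a bundle from every seed region (deterministic per-region derived
#' seeds) and tabulates the four fiber metrics.
#'
#' @param tf,fa tensor field and FA map from [dti_stage()].
#' @param regions named list of `seed_region`s from [build_seed_regions()].
#' @param config pipeline configuration.
#' @param subject subject identifier stored in the table.
#' @return list with `bundles` (named list) and `metrics` (long data.frame).
#' @export
track_stage <- function(tf, fa, regions, config = default_config(),
                        subject = 1L) {
  rows <- list()
  bundles <- list()
  for (i in seq_along(regions)) {
    rg <- regions[[i]]
    nm <- names(regions)[i]
    if (rg$empty) {
      met <- structure(list(fiber_count = 0L, mean_length = NA_real_,
                            mean_fa = NA_real_, mean_cs = NA_real_,
                            defined = FALSE), class = "bundle_metrics")
      bundles[[nm]] <- NULL
    } else {
      tp <- do.call(tracking_params, c(
        config$tracking,
        list(rng_seed = (config$rng_seed + 1009L * as.integer(subject) +
                           101L * i) %% .Machine$integer.max)))
      bd <- track_bundle(tf, fa, rg$mask, tp)
      bundles[[nm]] <- bd
      met <- bundle_metrics(bd, fa)
    }
    rows[[nm]] <- data.frame(subject = subject, side = rg$side,
                             distance = rg$distance,
                             n_seed_voxels = rg$n_voxels,
                             fiber_count = met$fiber_count,
                             mean_length = met$mean_length,
                             mean_fa = met$mean_fa, mean_cs = met$mean_cs)
  }
  list(bundles = bundles, metrics = do.call(rbind, c(rows, make.row.names = FALSE)))
}

#' Analyze one subject end to end
#'
#' Full PET/DTI chain on in-memory inputs (typically a [generate_phantom()]
#' result): asymmetry mapping, focus extraction, seed construction, tensor
#' fitting, tractography, and metric tabulation.
#'
#' @param phantom a `phantom` (or any list exposing `pet_activity`,
#'   `gm_prob`, `wm_prob`, `cerebellum_mask`, `dwi`).
#' @param config pipeline configuration.
#' @param subject subject identifier.
#' @param stages `"all"` or `"ai"` (stop after focus extraction).
#' @return list of class `subject_result`: the `ai_map_stage()` output plus
#'   (when tracking ran) `seeds`, `tf`, `fa`, `bundles`, `metrics`, `status`.
#' @export
run_subject <- function(phantom, config = default_config(), subject = 1L,
                        stages = c("all", "ai")) {
  stages <- match.arg(stages)
  res <- ai_map_stage(phantom$pet_activity, phantom$gm_prob,
                      phantom$cerebellum_mask, config)
  res$subject <- subject
  class(res) <- "subject_result"
  if (!res$roi$found || stages == "ai") return(res)
  wm_mask <- !is.na(phantom$wm_prob$data) &
    phantom$wm_prob$data >= config$seeds$wm_threshold
  spec <- seed_spec(config$seeds$voi_edge, config$seeds$distances,
                    config$seeds$cumulative)
  snap <- if (isTRUE(config$seeds$snap_contralateral)) res$gm_mask else NULL
  res$seeds <- build_seed_regions(res$roi, wm_mask, phantom$gm_prob, spec,
                                  midline_world_x = default_midline(phantom$gm_prob),
                                  snap_to_gm = snap)
  dts <- dti_stage(phantom$dwi, phantom$wm_prob, config)
  res$tf <- dts$tf
  res$fa <- dts$fa
  trk <- track_stage(dts$tf, dts$fa, res$seeds$regions, config, subject)
  res$bundles <- trk$bundles
  res$metrics <- trk$metrics
  res
}

#' @export
print.subject_result <- function(x, ...) {
  cat("<subject_result> status:", x$status, "\n")
  if (x$roi$found) print(x$roi)
  if (!is.null(x$metrics)) print(x$metrics, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Analyze a phantom cohort
#'
#' Generates (or reuses) each subject's phantom, runs the full per-subject
#' analysis, pools the fiber metrics, and builds the cohort asymmetry report
#' with Wilcoxon comparisons across seed distances.
#'
#' @param cohort a [generate_cohort()] result.
#' @param config pipeline configuration.
#' @param progress print one line per subject.
#' @return list of class `cohort_result`: `metrics` (pooled long table),
#'   `report` ([build_report()]), `statuses` (per-subject), `manifest`.
#' @export
run_cohort <- function(cohort, config = default_config(), progress = FALSE) {
  n <- length(cohort$specs)
  all_metrics <- list()
  statuses <- character(n)
  for (i in seq_len(n)) {
    ph <- if (!is.null(cohort$phantoms)) cohort$phantoms[[i]] else
      generate_phantom(cohort$specs[[i]])
    sr <- run_subject(ph, config, subject = i)
    statuses[i] <- sr$status
    if (!is.null(sr$metrics)) all_metrics[[length(all_metrics) + 1L]] <- sr$metrics
    if (progress)
      message(sprintf("subject %d/%d: %s", i, n, sr$status))
  }
  metrics <- do.call(rbind, all_metrics)
  report <- if (!is.null(metrics)) build_report(metrics) else NULL
  structure(list(metrics = metrics, report = report, statuses = statuses,
                 manifest = cohort$manifest),
            class = "cohort_result")
}

#' @export
print.cohort_result <- function(x, ...) {
  cat(sprintf("<cohort_result> %d subjects, %d with a detected focus\n",
              length(x$statuses), sum(x$statuses == "ok")))
  if (!is.null(x$report)) print(x$report)
  invisible(x)
}

#' Run the pipeline from a configuration, writing stage outputs
#'
#' File-based front end: reads or generates the inputs, executes every stage,
#' writes each stage's product (NIfTI maps, seed masks, metrics and report
#' CSV/JSON) under `out_dir`, and records an MD5 content hash per output in
#' `manifest.json`. Rerunning with the same configuration and seed reproduces
#' identical hashes. A run ending in `"no significant hypometabolism"` is a
#' clean terminal status, not an error.
#'
#' @param config YAML path or list (see [validate_config()]). `input` may be
#'   `phantom:` (spec overrides for [phantom_spec()]) or `paths:` with NIfTI
#'   and bval/bvec file locations (`pet`, `gm_prob`, `wm_prob`,
#'   `cerebellum_mask`, `dwi`, `bval`, `bvec`).
#' @param out_dir output directory.
#' @return the manifest list, invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  cfg <- validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(cfg$input$paths)) {
    p <- cfg$input$paths
    need <- c("pet", "gm_prob", "wm_prob", "cerebellum_mask")
    miss <- setdiff(need, names(p))
    if (length(miss)) stop("input/paths missing: ", paste(miss, collapse = ", "))
    for (f in unlist(p)) if (!file.exists(f)) stop("input file not found: ", f)
    phantom <- list(pet_activity = read_volume(p$pet),
                    gm_prob = read_volume(p$gm_prob),
                    wm_prob = read_volume(p$wm_prob),
                    cerebellum_mask = read_volume(p$cerebellum_mask)$data >= 0.5)
    if (!is.null(p$dwi)) {
      gt <- gradient_table(p$bval, p$bvec)
      img <- RNifti::readNifti(p$dwi)
      aff <- structure(RNifti::xform(img), class = NULL)
      phantom$dwi <- dwi_dataset(array(as.numeric(img), dim(img)), gt,
                                 abs(diag(aff[1:3, 1:3])), aff)
    }
  } else {
    spec <- do.call(phantom_spec,
                    c(cfg$input$phantom %||% list(),
                      if (is.null(cfg$input$phantom$rng_seed))
                        list(rng_seed = cfg$rng_seed)))
    phantom <- generate_phantom(spec)
    write_phantom(phantom, file.path(out_dir, "phantom"))
  }
  has_dwi <- !is.null(phantom$dwi)
  sr <- run_subject(phantom, cfg, subject = 1L,
                    stages = if (has_dwi) "all" else "ai")
  g <- sr$suv
  write_volume(sr$suv, file.path(out_dir, "suv.nii.gz"))
  suvr_out <- sr$suvr; suvr_out$data[is.na(suvr_out$data)] <- 0
  write_volume(suvr_out, file.path(out_dir, "suvr.nii.gz"))
  ai_out <- sr$ai; ai_out$data[is.na(ai_out$data)] <- 0
  write_volume(ai_out, file.path(out_dir, "ai.nii.gz"))
  if (!is.null(sr$zai)) {
    z_out <- sr$zai; z_out$data[is.na(z_out$data)] <- 0
    write_volume(z_out, file.path(out_dir, "zai.nii.gz"))
  }
  roi_summary <- list(status = sr$status, found = sr$roi$found,
                      voxel_count = sr$roi$voxel_count,
                      hemisphere = sr$roi$hemisphere,
                      centroid_world = sr$roi$centroid_world,
                      mean_zai = sr$roi$mean_zai, min_zai = sr$roi$min_zai,
                      critical_z = sr$threshold$critical_z_2dp,
                      df = sr$threshold$df)
  jsonlite::write_json(roi_summary, file.path(out_dir, "roi.json"),
                       auto_unbox = TRUE, digits = NA)
  if (sr$roi$found) {
    write_mask(volume3d(sr$roi$mask, g$spacing, g$affine),
               file.path(out_dir, "roi_mask.nii.gz"))
  }
  if (!is.null(sr$seeds)) {
    sd_dir <- file.path(out_dir, "seeds")
    dir.create(sd_dir, showWarnings = FALSE)
    centres <- list(ipsilateral = sr$seeds$voi$centre,
                    contralateral = sr$seeds$contra_centre)
    counts <- lapply(sr$seeds$regions, function(r) r$n_voxels)
    jsonlite::write_json(list(voi_centres = centres, region_voxels = counts),
                         file.path(sd_dir, "seeds.json"), auto_unbox = TRUE,
                         digits = NA)
    for (nm in names(sr$seeds$regions))
      write_mask(volume3d(sr$seeds$regions[[nm]]$mask, g$spacing, g$affine),
                 file.path(sd_dir, paste0(nm, ".nii.gz")))
  }
  if (!is.null(sr$fa))
    write_volume(sr$fa, file.path(out_dir, "fa.nii.gz"))
  if (!is.null(sr$bundles)) {
    tr_dir <- file.path(out_dir, "tracks")
    dir.create(tr_dir, showWarnings = FALSE)
    for (nm in names(sr$bundles))
      write_bundle_jsonl(sr$bundles[[nm]], file.path(tr_dir, paste0(nm, ".jsonl")))
  }
  if (!is.null(sr$metrics)) {
    utils::write.csv(sr$metrics, file.path(out_dir, "metrics.csv"),
                     row.names = FALSE)
    write_report(build_report(sr$metrics), file.path(out_dir, "report"))
  }
  files <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  files <- setdiff(files, file.path(out_dir, "manifest.json"))
  hashes <- tools::md5sum(files)
  names(hashes) <- sub(paste0("^", out_dir, "/?"), "", names(hashes))
  manifest <- list(status = sr$status, rng_seed = cfg$rng_seed,
                   outputs = as.list(hashes))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
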