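#' Seed-region specification
#'
#' Geometry of the white-matter seeding around the PET focus: a cubic volume
#' of interest (VOI) placed at the WM-facing edge of the ROI, then grown into
#' WM at graded distances.
#'
#' @param voi_edge VOI cube edge, mm (default 3, i.e. 3 x 3 x 3 mm^3).
#' @param distances strictly increasing dilation distances in mm
#'   (default `c(3, 9, 15)`).
#' @param cumulative if `TRUE` (default) the region at distance d contains all
#'   WM within d mm of the VOI (nested regions); if `FALSE`, disjoint shells
#'   between consecutive distances (sensitivity-analysis mode).
#' @return list of class `seed_spec`.
#' @export
seed_spec <- function(voi_edge = 3, distances = c(3, 9, 15), cumulative = TRUE) {
  if (!is.finite(voi_edge) || voi_edge <= 0) stop("`voi_edge` must be > 0 mm")
  distances <- as.numeric(distances)
  if (any(distances <= 0) || is.unsorted(distances, strictly = TRUE))
    stop("`distances` must be positive and strictly increasing")
  structure(list(voi_edge = voi_edge, distances = distances,
                 cumulative = cumulative),
            class = "seed_spec")
}

# Euclidean distance (world mm) from points to an axis-aligned cube.
point_to_cube_distance <- function(pts, centre, edge) {
  h <- edge / 2
  dx <- pmax(abs(pts[, 1] - centre[1]) - h, 0)
  dy <- pmax(abs(pts[, 2] - centre[2]) - h, 0)
  dz <- pmax(abs(pts[, 3] - centre[3]) - h, 0)
  sqrt(dx^2 + dy^2 + dz^2)
}

#' Place the seeding VOI at the WM-facing edge of the PET ROI
#'
#' The VOI centre is the ROI voxel minimizing the Euclidean distance to the
#' nearest WM voxel centre (the point of the ROI "directly adjacent to the
#' closest WM area"). Ties are broken by proximity to the ROI centroid, then
#' by the smallest linear voxel index, so placement is deterministic.
#'
#' @param roi a `pet_roi` from [extract_roi()] (or any list with a logical
#'   `mask`).
#' @param wm_mask logical WM mask on the same grid.
#' @param geometry a `volume3d` (or `tensor_field`) carrying the shared
#'   affine/spacing.
#' @param spec a [seed_spec()].
#' @return list with `centre` (world mm), `centre_index` (voxel), `voi_mask`
#'   (voxels whose centres fall in the VOI cube, clipped to grid) and
#'   `distance_to_wm` (mm).
#' @export
place_voi <- function(roi, wm_mask, geometry, spec = seed_spec()) {
  roi_mask <- roi$mask
  if (!any(roi_mask)) stop("ROI mask is empty")
  if (!any(wm_mask)) stop("WM mask is empty")
  roi_idx <- which(roi_mask)
  roi_ijk <- which(roi_mask, arr.ind = TRUE)
  roi_w <- voxel_to_world(geometry, roi_ijk)
  wm_w <- voxel_to_world(geometry, which(wm_mask, arr.ind = TRUE))
  # min distance from each ROI voxel to WM, chunked to bound memory
  dmin <- rep(Inf, nrow(roi_w))
  chunk <- max(1L, floor(2e6 / nrow(roi_w)))
  for (s in seq(1, nrow(wm_w), by = chunk)) {
    e <- min(s + chunk - 1, nrow(wm_w))
    blk <- wm_w[s:e, , drop = FALSE]
    d2 <- outer(roi_w[, 1], blk[, 1], "-")^2 +
      outer(roi_w[, 2], blk[, 2], "-")^2 +
      outer(roi_w[, 3], blk[, 3], "-")^2
    dmin <- pmin(dmin, sqrt(apply(d2, 1, min)))
  }
  best <- which(dmin == min(dmin))
  if (length(best) > 1) {
    centroid <- colMeans(roi_w)
    dc <- rowSums((roi_w[best, , drop = FALSE] -
                     matrix(centroid, length(best), 3, byrow = TRUE))^2)
    best <- best[dc == min(dc)]
    if (length(best) > 1) best <- best[which.min(roi_idx[best])]
  }
  centre <- roi_w[best, ]
  d <- dim(roi_mask)
  allw <- voxel_to_world(geometry, as.matrix(expand.grid(i = seq_len(d[1]),
                                                         j = seq_len(d[2]),
                                                         k = seq_len(d[3]))))
  inside <- abs(allw[, 1] - centre[1]) <= spec$voi_edge / 2 &
    abs(allw[, 2] - centre[2]) <= spec$voi_edge / 2 &
    abs(allw[, 3] - centre[3]) <= spec$voi_edge / 2
  list(centre = as.numeric(centre),
       centre_index = as.integer(roi_ijk[best, ]),
       voi_mask = array(inside, d),
       distance_to_wm = dmin[best])
}

#' Grow a seed region from the VOI into white matter
#'
#' The region at distance d is the set of WM voxels whose centre lies within
#' d mm (Euclidean, world space) of the VOI cube surface — a distance-ball
#' dilation intersected with the WM mask. Regions are nested in d by
#' construction. An empty result is returned as a flagged empty region, not
#' an error (tracking is skipped for that distance).
#'
#' @param voi_centre VOI centre, world mm.
#' @param wm_mask logical WM mask.
#' @param geometry `volume3d`/`tensor_field` carrying the shared geometry.
#' @param distance dilation distance, mm (> 0).
#' @param voi_edge VOI cube edge, mm.
#' @param side label stored on the region (`"ipsilateral"`/`"contralateral"`).
#' @param min_distance lower distance bound (exclusive) for shell mode;
#'   default 0 gives the cumulative ball.
#' @return list of class `seed_region`: `mask`, `side`, `distance`,
#'   `source_voi_centre`, `n_voxels`, `empty`.
#' @export
dilate_into_wm <- function(voi_centre, wm_mask, geometry, distance,
                           voi_edge = 3, side = "ipsilateral",
                           min_distance = 0) {
  if (!is.finite(distance) || distance <= 0) stop("`distance` must be > 0 mm")
  wm_ijk <- which(wm_mask, arr.ind = TRUE)
  mask <- array(FALSE, dim(wm_mask))
  if (nrow(wm_ijk)) {
    w <- voxel_to_world(geometry, wm_ijk)
    dd <- point_to_cube_distance(w, voi_centre, voi_edge)
    sel <- dd <= distance & dd > min_distance
    mask[which(wm_mask)[sel]] <- TRUE
  }
  structure(list(mask = mask, side = side, distance = distance,
                 source_voi_centre = as.numeric(voi_centre),
                 n_voxels = sum(mask), empty = !any(mask)),
            class = "seed_region")
}

#' @export
print.seed_region <- function(x, ...) {
  cat(sprintf("<seed_region> %s, %g mm: %d WM voxels%s\n", x$side, x$distance,
              x$n_voxels, if (x$empty) " (empty)" else ""))
  invisible(x)
}

#' Mirror the VOI centre into the contralateral hemisphere
#'
#' Reflects the VOI centre about the sagittal plane x = midline — an automated
#' stand-in for manual placement of the contralateral control VOI. Optionally
#' snaps the reflected centre to the nearest GM voxel centre to tolerate small
#' residual anatomical asymmetries.
#'
#' @param voi_centre world-mm VOI centre.
#' @param geometry `volume3d`/`tensor_field` carrying the grid.
#' @param midline_world_x sagittal midline, mm.
#' @param snap_to_gm optional logical GM mask; if supplied, the mirrored
#'   centre is moved to the nearest GM voxel centre.
#' @return world-mm coordinates of the contralateral VOI centre.
#' @export
mirror_contralateral <- function(voi_centre, geometry, midline_world_x = 0,
                                 snap_to_gm = NULL) {
  centre <- as.numeric(voi_centre)
  centre[1] <- 2 * midline_world_x - centre[1]
  d <- dim(if (is_volume3d(geometry)) geometry$data else geometry$mask)
  v <- world_to_voxel(geometry, matrix(centre, 1, 3))
  if (any(v < 0.5) || any(v > d + 0.5))
    stop("mirrored VOI centre falls outside the grid")
  if (!is.null(snap_to_gm) && any(snap_to_gm)) {
    gw <- voxel_to_world(geometry, which(snap_to_gm, arr.ind = TRUE))
    dd <- (gw[, 1] - centre[1])^2 + (gw[, 2] - centre[2])^2 +
      (gw[, 3] - centre[3])^2
    centre <- as.numeric(gw[which.min(dd), ])
  }
  centre
}

#' Build all ipsilateral and contralateral seed regions
#'
#' Convenience wrapper: places the VOI at the ROI's WM-facing edge, mirrors it
#' about the midline, and dilates both into WM at every distance of the spec.
#'
#' @inheritParams place_voi
#' @param midline_world_x sagittal midline, mm.
#' @param snap_to_gm optional GM mask for contralateral snapping.
#' @return list with `voi` (from [place_voi()]), `contra_centre`, and
#'   `regions`: a list of `seed_region`s keyed `"<side>_<distance>"`.
#' @export
build_seed_regions <- function(roi, wm_mask, geometry, spec = seed_spec(),
                               midline_world_x = 0, snap_to_gm = NULL) {
  voi <- place_voi(roi, wm_mask, geometry, spec)
  contra <- mirror_contralateral(voi$centre, geometry, midline_world_x,
                                 snap_to_gm)
  regions <- list()
  for (i in seq_along(spec$distances)) {
    dist <- spec$distances[i]
    lo <- if (spec$cumulative || i == 1L) 0 else spec$distances[i - 1L]
    regions[[paste0("ipsilateral_", dist)]] <-
      dilate_into_wm(voi$centre, wm_mask, geometry, dist, spec$voi_edge,
                     "ipsilateral", lo)
    regions[[paste0("contralateral_", dist)]] <-
      dilate_into_wm(contra, wm_mask, geometry, dist, spec$voi_edge,
                     "contralateral", lo)
  }
  list(voi = voi, contra_centre = contra, regions = regions)
}
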