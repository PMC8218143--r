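#' Scalar 3-D volume with world geometry
#'
#' `volume3d()` wraps a numeric 3-D array together with a voxel-to-world
#' affine and voxel spacing. World coordinates are in millimetres, RAS
#' orientation; voxel indexing follows the NIfTI convention (the affine maps
#' 0-based voxel indices to world mm). All pipeline stages share one
#' coordinate space.
#'
#' @param data numeric (or logical) 3-D array.
#' @param spacing voxel edge lengths in mm, length 3, all positive.
#' @param affine 4x4 voxel-index (0-based) to world-mm matrix. Defaults to a
#'   diagonal affine that centres the grid on the world origin, which places
#'   the sagittal midplane at world x = 0 for grids built symmetrically.
#' @return An object of class `volume3d`: a list with elements `data`,
#'   `affine`, `spacing`.
#' @examples
#' v <- volume3d(array(0, c(4, 4, 4)), spacing = c(2, 2, 2))
#' dim(v$data)
#' @export
volume3d <- function(data, spacing = c(1, 1, 1), affine = NULL) {
  if (length(dim(data)) != 3L)
    stop("`data` must be a 3-D array")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three positive voxel sizes in mm")
  if (is.null(affine)) {
    d <- dim(data)
    origin <- -(d - 1) / 2 * spacing
    affine <- rbind(cbind(diag(spacing), origin), c(0, 0, 0, 1))
    dimnames(affine) <- NULL
  }
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)) || abs(det(affine)) < .Machine$double.eps)
    stop("`affine` must be an invertible 4x4 matrix")
  structure(list(data = data, affine = affine, spacing = spacing),
            class = "volume3d")
}

#' @export
print.volume3d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume3d> %d x %d x %d voxels, spacing %s mm\n",
              d[1], d[2], d[3], paste(signif(x$spacing, 4), collapse = " x ")))
  rng <- suppressWarnings(range(x$data, na.rm = TRUE))
  cat(sprintf("  data range: [%g, %g], %d NA\n", rng[1], rng[2],
              sum(is.na(x$data))))
  invisible(x)
}

is_volume3d <- function(x) inherits(x, "volume3d")

#' Volume of one voxel in mm^3
#' @param vol a `volume3d`.
#' @return scalar, mm^3.
#' @export
voxel_volume <- function(vol) prod(vol$spacing)

same_geometry <- function(a, b, tol = 1e-6) {
  all(dim(a$data) == dim(b$data)) && max(abs(a$affine - b$affine)) < tol
}

#' Convert voxel indices to world coordinates
#'
#' @param vol a `volume3d`.
#' @param ijk n x 3 matrix of 1-based (R) voxel indices; may be fractional.
#' @return n x 3 matrix of world mm coordinates.
#' @export
voxel_to_world <- function(vol, ijk) {
  ijk <- matrix(as.numeric(ijk), ncol = 3L)
  h <- cbind(ijk - 1, 1)            # NIfTI affines are 0-based
  out <- h %*% t(vol$affine)
  out[, 1:3, drop = FALSE]
}

#' Convert world coordinates to (fractional) voxel indices
#'
#' @inheritParams voxel_to_world
#' @param xyz n x 3 matrix of world mm coordinates.
#' @return n x 3 matrix of 1-based fractional voxel indices.
#' @export
world_to_voxel <- function(vol, xyz) {
  xyz <- matrix(as.numeric(xyz), ncol = 3L)
  h <- cbind(xyz, 1) %*% t(solve(vol$affine))
  h[, 1:3, drop = FALSE] + 1
}

# World-x coordinates of all voxel centres along the first axis (assumes an
# axis-aligned affine, which every pipeline grid uses).
axis_world_x <- function(vol) {
  n <- dim(vol$data)[1]
  vol$affine[1, 1] * (seq_len(n) - 1) + vol$affine[1, 4]
}

#' Default sagittal midline of a grid
#'
#' The world-x coordinate of the grid centre (halfway between the first and
#' last voxel centre along x). For template-like grids built symmetrically
#' about the origin this is exactly 0.
#'
#' @param vol a `volume3d`.
#' @return world-x position of the midline in mm.
#' @export
default_midline <- function(vol) {
  xs <- axis_world_x(vol)
  (xs[1] + xs[length(xs)]) / 2
}

#' Trilinear sampling of a volume at world points
#'
#' Values at points outside the grid are `NA`. `NA` voxels propagate to any
#' sample whose 8-neighbour support touches them.
#'
#' @param vol a `volume3d`.
#' @param xyz n x 3 matrix of world mm coordinates.
#' @return numeric vector of length n.
#' @export
sample_trilinear <- function(vol, xyz) {
  v <- world_to_voxel(vol, xyz)
  d <- dim(vol$data)
  i0 <- floor(v)
  f <- v - i0
  out <- rep(NA_real_, nrow(v))
  ok <- i0[, 1] >= 1 & i0[, 2] >= 1 & i0[, 3] >= 1 &
    (i0[, 1] + (f[, 1] > 0)) <= d[1] &
    (i0[, 2] + (f[, 2] > 0)) <= d[2] &
    (i0[, 3] + (f[, 3] > 0)) <= d[3]
  ok[is.na(ok)] <- FALSE
  if (!any(ok)) return(out)
  i0 <- i0[ok, , drop = FALSE]; f <- f[ok, , drop = FALSE]
  # clamp the upper corner for samples sitting exactly on the last plane
  i1 <- pmin(i0 + 1, matrix(d, nrow(i0), 3, byrow = TRUE))
  arr <- vol$data
  idx <- function(a, b, c) arr[cbind(a, b, c)]
  acc <- (1 - f[, 1]) * (1 - f[, 2]) * (1 - f[, 3]) * idx(i0[, 1], i0[, 2], i0[, 3]) +
    f[, 1] * (1 - f[, 2]) * (1 - f[, 3]) * idx(i1[, 1], i0[, 2], i0[, 3]) +
    (1 - f[, 1]) * f[, 2] * (1 - f[, 3]) * idx(i0[, 1], i1[, 2], i0[, 3]) +
    (1 - f[, 1]) * (1 - f[, 2]) * f[, 3] * idx(i0[, 1], i0[, 2], i1[, 3]) +
    f[, 1] * f[, 2] * (1 - f[, 3]) * idx(i1[, 1], i1[, 2], i0[, 3]) +
    f[, 1] * (1 - f[, 2]) * f[, 3] * idx(i1[, 1], i0[, 2], i1[, 3]) +
    (1 - f[, 1]) * f[, 2] * f[, 3] * idx(i0[, 1], i1[, 2], i1[, 3]) +
    f[, 1] * f[, 2] * f[, 3] * idx(i1[, 1], i1[, 2], i1[, 3])
  out[ok] <- acc
  out
}

#' Reflect a volume about a sagittal plane
#'
#' Maps world point (x, y, z) to (2 * midline - x, y, z). When the reflection
#' maps voxel centres onto voxel centres (grid-aligned midline) the flip is an
#' exact index reversal; otherwise values are resampled by trilinear
#' interpolation and points reflected off-grid become `NA`.
#'
#' @param vol a `volume3d`.
#' @param midline_world_x sagittal plane position in world mm. Defaults to the
#'   grid centre ([default_midline()]).
#' @return a `volume3d` with the same geometry.
#' @export
flip_sagittal <- function(vol, midline_world_x = default_midline(vol)) {
  xs <- axis_world_x(vol)
  lo <- min(xs) - abs(vol$spacing[1]) / 2
  hi <- max(xs) + abs(vol$spacing[1]) / 2
  if (!is.finite(midline_world_x) || midline_world_x < lo || midline_world_x > hi)
    stop("midline (", midline_world_x, " mm) lies outside the volume world-x extent [",
         signif(lo, 6), ", ", signif(hi, 6), "]")
  xr <- 2 * midline_world_x - xs
  # grid-aligned fast path: reflected centres coincide with centres, reversed
  if (max(abs(xr - rev(xs))) < 1e-6 * max(1, abs(vol$spacing[1]))) {
    d <- dim(vol$data)
    out <- vol$data[d[1]:1, , , drop = FALSE]
    return(volume3d(out, vol$spacing, vol$affine))
  }
  d <- dim(vol$data)
  grid <- as.matrix(expand.grid(i = seq_len(d[1]), j = seq_len(d[2]),
                                k = seq_len(d[3])))
  w <- voxel_to_world(vol, grid)
  w[, 1] <- 2 * midline_world_x - w[, 1]
  vals <- sample_trilinear(vol, w)
  volume3d(array(vals, d), vol$spacing, vol$affine)
}

#' Symmetrize a volume about the sagittal midline
#'
#' Mean of the image and its sagittal reflection; the result is invariant
#' under [flip_sagittal()] (exactly so on a grid-aligned midline). This is how
#' a hemispherically symmetric reference template is built before asymmetry
#' mapping.
#'
#' @inheritParams flip_sagittal
#' @return a `volume3d`.
#' @export
make_symmetric_template <- function(vol, midline_world_x = default_midline(vol)) {
  f <- flip_sagittal(vol, midline_world_x)
  volume3d((vol$data + f$data) / 2, vol$spacing, vol$affine)
}

gaussian_kernel_1d <- function(sigma_vox) {
  if (sigma_vox <= 0) return(1)
  r <- max(1L, ceiling(4 * sigma_vox))
  x <- (-r):r
  k <- exp(-x^2 / (2 * sigma_vox^2))
  k / sum(k)
}

# 1-D convolution along the first dimension of a matrix, reflect boundary.
conv1_reflect <- function(mat, kernel) {
  n <- nrow(mat)
  r <- (length(kernel) - 1L) / 2L
  if (r == 0L) return(mat * kernel)
  # reflect-about-edge index sequence (abcd -> dcba|abcd|dcba), re-reflecting
  # while the kernel support is wider than the grid
  idx <- seq.int(-r + 1L, n + r)
  repeat {
    below <- idx < 1L
    above <- idx > n
    if (!any(below) && !any(above)) break
    idx[below] <- 1L - idx[below]
    idx[above] <- 2L * n + 1L - idx[above]
  }
  pad <- mat[idx, , drop = FALSE]
  out <- matrix(0, n, ncol(mat))
  for (k in seq_along(kernel))
    out <- out + kernel[k] * pad[seq.int(k, k + n - 1L), , drop = FALSE]
  out
}

#' Gaussian smoothing of a volume
#'
#' Separable discrete Gaussian convolution. The kernel width is given as a
#' full-width-at-half-maximum in mm and converted per axis to
#' `sigma = fwhm / (2 sqrt(2 log 2)) / spacing` voxels, so anisotropic voxels
#' are handled correctly. Boundary mode is reflection, which preserves the
#' global sum of compactly supported signals.
#'
#' @param vol a `volume3d` with finite data.
#' @param fwhm kernel full width at half maximum, mm; `0` is the identity.
#' @return a smoothed `volume3d`.
#' @export
gaussian_smooth <- function(vol, fwhm) {
  if (!is.finite(fwhm) || fwhm < 0) stop("`fwhm` must be >= 0 mm")
  if (fwhm == 0) return(vol)
  sig <- fwhm / (2 * sqrt(2 * log(2))) / vol$spacing
  d <- dim(vol$data)
  a <- vol$data
  for (ax in 1:3) {
    k <- gaussian_kernel_1d(sig[ax])
    if (length(k) == 1L) next
    perm <- c(ax, setdiff(1:3, ax))
    ap <- aperm(a, perm)
    dp <- dim(ap)
    m <- conv1_reflect(matrix(ap, dp[1], dp[2] * dp[3]), k)
    a <- aperm(array(m, dp), order(perm))
  }
  volume3d(a, vol$spacing, vol$affine)
}

#' Resample a volume to a new isotropic-or-not spacing
#'
#' Trilinear resampling onto a grid covering the same world extent. The world
#' extent is taken as the union of voxel cells (first centre - spacing/2 to
#' last centre + spacing/2); the new grid has `ceiling(extent / target)`
#' voxels per axis with centres at `start + (k - 1/2) * target`, so a 2 mm to
#' 1 mm upsampling exactly doubles each dimension.
#'
#' @param vol a `volume3d`.
#' @param target_spacing new voxel sizes in mm (scalar or length 3).
#' @param method `"trilinear"` (scalar volumes) or `"nearest"` (masks).
#' @return a `volume3d` on the new grid.
#' @export
resample <- function(vol, target_spacing, method = c("trilinear", "nearest")) {
  method <- match.arg(method)
  ts <- rep(as.numeric(target_spacing), length.out = 3)
  if (any(!is.finite(ts)) || any(ts <= 0)) stop("`target_spacing` must be > 0")
  if (max(abs(ts - vol$spacing)) < 1e-9) return(vol)
  d <- dim(vol$data)
  # world position of the low cell edge along each axis (axis-aligned affine)
  orig <- vol$affine[1:3, 4]
  step <- diag(vol$affine[1:3, 1:3])
  lo <- orig - step / 2
  extent <- abs(step) * d
  nd <- as.integer(ceiling(extent / ts - 1e-9))
  centres <- lapply(1:3, function(ax) lo[ax] + sign(step[ax]) * ((seq_len(nd[ax]) - 0.5) * ts[ax]))
  grid <- as.matrix(expand.grid(x = centres[[1]], y = centres[[2]], z = centres[[3]]))
  vals <- if (method == "trilinear") {
    sample_trilinear(vol, grid)
  } else {
    v <- round(world_to_voxel(vol, grid))
    ok <- v[, 1] >= 1 & v[, 1] <= d[1] & v[, 2] >= 1 & v[, 2] <= d[2] &
      v[, 3] >= 1 & v[, 3] <= d[3]
    out <- rep(NA_real_, nrow(v))
    out[ok] <- vol$data[v[ok, , drop = FALSE]]
    out
  }
  aff <- diag(4)
  diag(aff)[1:3] <- sign(step) * ts
  aff[1:3, 4] <- lo + sign(step) * ts / 2
  volume3d(array(vals, nd), ts, aff)
}

neighbor_offsets <- function(connectivity) {
  stopifnot(connectivity %in% c(6L, 18L, 26L))
  g <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  ord <- rowSums(abs(g))
  keep <- switch(as.character(connectivity),
                 "6"  = ord == 1,
                 "18" = ord >= 1 & ord <= 2,
                 "26" = ord >= 1)
  g[keep, , drop = FALSE]
}

#' Label connected components of a 3-D mask
#'
#' Breadth-first labelling under 6-, 18-, or 26-neighbour connectivity.
#' Components are reported sorted by voxel count (descending); ties are broken
#' by the smallest minimum linear voxel index, so the ordering is
#' deterministic.
#'
#' @param mask logical 3-D array.
#' @param connectivity 6, 18 or 26 (default 26, the neuroimaging standard for
#'   focal clusters).
#' @return list with `labels` (integer array, 0 = background; label k is the
#'   k-th largest component), `sizes` (voxel counts, sorted descending) and
#'   `n` (component count).
#' @export
connected_components <- function(mask, connectivity = 26L) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3L)
  d <- dim(mask)
  offs <- neighbor_offsets(as.integer(connectivity))
  labels <- array(0L, d)
  remaining <- which(mask)
  comp_sizes <- integer(0)
  comp_minidx <- integer(0)
  lab <- 0L
  seen <- array(FALSE, d)
  while (length(remaining)) {
    seed <- remaining[1]
    lab <- lab + 1L
    frontier <- seed
    seen[seed] <- TRUE
    members <- seed
    while (length(frontier)) {
      co <- arrayInd(frontier, d)
      nb <- do.call(rbind, lapply(seq_len(nrow(offs)), function(r)
        cbind(co[, 1] + offs[r, 1], co[, 2] + offs[r, 2], co[, 3] + offs[r, 3])))
      ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
        nb[, 3] >= 1 & nb[, 3] <= d[3]
      nb <- nb[ok, , drop = FALSE]
      lin <- unique((nb[, 3] - 1L) * d[1] * d[2] + (nb[, 2] - 1L) * d[1] + nb[, 1])
      lin <- lin[mask[lin] & !seen[lin]]
      seen[lin] <- TRUE
      members <- c(members, lin)
      frontier <- lin
    }
    labels[members] <- lab
    comp_sizes <- c(comp_sizes, length(members))
    comp_minidx <- c(comp_minidx, min(members))
    remaining <- remaining[!seen[remaining]]
  }
  ord <- order(-comp_sizes, comp_minidx)
  relab <- integer(lab)
  relab[ord] <- seq_len(lab)
  labels[labels > 0L] <- relab[labels[labels > 0L]]
  list(labels = labels, sizes = comp_sizes[ord], n = lab)
}

#' Read / write NIfTI volumes
#'
#' Thin wrappers over \pkg{RNifti} that carry the qform/sform affine and voxel
#' spacing into a [volume3d()]. Masks are written as uint8.
#'
#' @param path NIfTI file (`.nii` / `.nii.gz`).
#' @return `read_volume()` returns a `volume3d`.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  aff <- matrix(as.numeric(RNifti::xform(img)), 4, 4)
  spacing <- abs(c(aff[1, 1], aff[2, 2], aff[3, 3]))
  volume3d(array(as.numeric(img), dim(img)[1:3]), spacing, aff)
}

#' @rdname read_volume
#' @param vol a `volume3d` (for `write_mask`, logical data).
#' @param datatype NIfTI storage type passed to [RNifti::writeNifti()].
#' @export
write_volume <- function(vol, path, datatype = "double") {
  img <- nifti_with_affine(vol$data, vol$affine, vol$spacing)
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

# Attach a voxel->world affine (sform, code 2) and pixdim to a data array.
nifti_with_affine <- function(data, affine, spacing) {
  RNifti::updateNifti(data, template = list(
    srow_x = affine[1, ], srow_y = affine[2, ], srow_z = affine[3, ],
    sform_code = 2L, qform_code = 0L,
    pixdim = c(1, spacing, rep(1, 4))))
}

#' @rdname read_volume
#' @export
write_mask <- function(vol, path) {
  v <- volume3d(array(as.numeric(vol$data), dim(vol$data)), vol$spacing, vol$affine)
  write_volume(v, path, datatype = "uint8")
}
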