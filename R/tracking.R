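#' Deterministic tractography parameters
#'
#' Settings for principal-eigenvector streamline integration. Defaults are
#' standard deterministic-tractography values; all are deliberately exposed
#' because termination criteria materially shape fiber metrics.
#'
#' @param step integration step, mm (must not exceed the smallest voxel size
#'   of the tracked field).
#' @param max_angle maximum turning angle between consecutive steps, degrees,
#'   in (0, 90).
#' @param fa_stop FA termination threshold.
#' @param min_length,max_length retained streamline length bounds, mm.
#' @param seeds_per_voxel jittered seed points drawn per seed-region voxel.
#' @param rng_seed integer seed making the jitter (the only randomness)
#'   reproducible.
#' @param interp direction-field interpolation: `"nearest"` (sign-coherent
#'   nearest-neighbour tensor, default) or `"trilinear"` (component-wise
#'   interpolated, renormalized principal eigenvector).
#' @param integrator `"euler"` (default) or `"rk4"`.
#' @return list of class `tracking_params`.
#' @export
tracking_params <- function(step = 0.5, max_angle = 45, fa_stop = 0.10,
                            min_length = 10, max_length = 250,
                            seeds_per_voxel = 8L, rng_seed = 1L,
                            interp = c("nearest", "trilinear"),
                            integrator = c("euler", "rk4")) {
  interp <- match.arg(interp)
  integrator <- match.arg(integrator)
  if (!is.finite(step) || step <= 0) stop("`step` must be > 0 mm")
  if (!is.finite(max_angle) || max_angle <= 0 || max_angle >= 90)
    stop("`max_angle` must lie in (0, 90) degrees")
  if (min_length < 0 || max_length <= min_length)
    stop("need 0 <= min_length < max_length")
  if (seeds_per_voxel < 1) stop("`seeds_per_voxel` must be >= 1")
  structure(list(step = step, max_angle = max_angle, fa_stop = fa_stop,
                 min_length = min_length, max_length = max_length,
                 seeds_per_voxel = as.integer(seeds_per_voxel),
                 rng_seed = as.integer(rng_seed), interp = interp,
                 integrator = integrator),
            class = "tracking_params")
}

# Field accessor: maps an N x 3 matrix of world positions to the local
# principal direction and FA. Nearest-neighbour lookup keeps masks crisp;
# trilinear interpolates e1 component-wise and renormalizes.
make_field_lookup <- function(tf, fa, interp) {
  dims <- dim(tf$mask)
  inv <- solve(tf$affine)
  e1x <- tf$e1[, , , 1]; e1y <- tf$e1[, , , 2]; e1z <- tf$e1[, , , 3]
  fav <- fa$data
  to_voxel <- function(pos) {
    h <- cbind(pos, 1) %*% t(inv)
    h[, 1:3, drop = FALSE] + 1
  }
  if (interp == "nearest") {
    function(pos) {
      v <- round(to_voxel(pos))
      ok <- v[, 1] >= 1 & v[, 1] <= dims[1] & v[, 2] >= 1 & v[, 2] <= dims[2] &
        v[, 3] >= 1 & v[, 3] <= dims[3]
      n <- nrow(pos)
      fav_out <- rep(-Inf, n)
      dir <- matrix(0, n, 3)
      if (any(ok)) {
        lin <- (v[ok, 3] - 1) * dims[1] * dims[2] + (v[ok, 2] - 1) * dims[1] + v[ok, 1]
        fav_out[ok] <- fav[lin]
        dir[ok, ] <- cbind(e1x[lin], e1y[lin], e1z[lin])
      }
      list(ok = ok & rowSums(dir^2) > 0, fa = fav_out, dir = dir)
    }
  } else {
    favol <- fa
    e1vols <- list(volume3d(e1x, tf$spacing, tf$affine),
                   volume3d(e1y, tf$spacing, tf$affine),
                   volume3d(e1z, tf$spacing, tf$affine))
    function(pos) {
      f <- sample_trilinear(favol, pos)
      d <- cbind(sample_trilinear(e1vols[[1]], pos),
                 sample_trilinear(e1vols[[2]], pos),
                 sample_trilinear(e1vols[[3]], pos))
      nrm <- sqrt(rowSums(d^2))
      ok <- !is.na(f) & !is.na(nrm) & nrm > 1e-8
      d[ok, ] <- d[ok, , drop = FALSE] / nrm[ok]
      d[!ok, ] <- 0
      f[is.na(f)] <- -Inf
      list(ok = ok, fa = f, dir = d)
    }
  }
}

# Integrate one half-track for all seeds simultaneously. Returns, per seed,
# the matrix of positions visited after the seed point.
propagate_half <- function(seeds, init_dir, lookup, params) {
  n <- nrow(seeds)
  max_steps <- ceiling(params$max_length / params$step)
  cos_max <- cos(params$max_angle * pi / 180)
  pos <- seeds
  dir <- init_dir
  active <- seq_len(n)
  counts <- integer(n)
  snaps <- vector("list", max_steps)
  step_dir <- function(p, d) {
    if (params$integrator == "euler") return(d)
    # RK4 on the sign-coherent direction field
    align <- function(q, ref) {
      s <- sign(rowSums(q$dir * ref)); s[s == 0] <- 1
      q$dir * s
    }
    k1 <- d
    k2 <- align(lookup(p + params$step / 2 * k1), d)
    k3 <- align(lookup(p + params$step / 2 * k2), d)
    k4 <- align(lookup(p + params$step * k3), d)
    v <- (k1 + 2 * k2 + 2 * k3 + k4) / 6
    nrm <- sqrt(rowSums(v^2))
    keep <- nrm > 1e-8
    v[keep, ] <- v[keep, , drop = FALSE] / nrm[keep]
    v[!keep, ] <- d[!keep, , drop = FALSE]
    v
  }
  for (t in seq_len(max_steps)) {
    if (!length(active)) break
    newpos <- pos + params$step * step_dir(pos, dir)
    lk <- lookup(newpos)
    alive <- lk$ok & lk$fa >= params$fa_stop
    if (any(alive)) {
      d_new <- lk$dir[alive, , drop = FALSE]
      d_old <- dir[alive, , drop = FALSE]
      s <- sign(rowSums(d_new * d_old)); s[s == 0] <- 1
      d_new <- d_new * s
      cosang <- rowSums(d_new * d_old)
      turn_ok <- cosang >= cos_max
      # the step lands in valid tissue: record it, then stop sharp turners
      rec <- active[alive]
      snaps[[t]] <- list(idx = rec, pos = newpos[alive, , drop = FALSE])
      counts[rec] <- counts[rec] + 1L
      keep <- which(alive)[turn_ok]
      pos <- newpos[keep, , drop = FALSE]
      dir <- d_new[turn_ok, , drop = FALSE]
      active <- active[keep]
    } else {
      active <- integer(0)
    }
  }
  # reconstruct per-seed point matrices
  out <- lapply(counts, function(k) matrix(NA_real_, k, 3))
  cursor <- integer(n)
  for (t in seq_len(max_steps)) {
    sn <- snaps[[t]]
    if (is.null(sn)) next
    for (r in seq_along(sn$idx)) {
      id <- sn$idx[r]
      cursor[id] <- cursor[id] + 1L
      out[[id]][cursor[id], ] <- sn$pos[r, ]
    }
  }
  out
}

track_from_seeds <- function(tf, fa, seeds, params) {
  if (params$step > min(tf$spacing) + 1e-9)
    stop("step (", params$step, " mm) exceeds the smallest voxel size (",
         min(tf$spacing), " mm)")
  lookup <- make_field_lookup(tf, fa, params$interp)
  lk <- lookup(seeds)
  valid <- lk$ok & lk$fa >= params$fa_stop
  n_rejected_seed <- sum(!valid)
  streamlines <- list()
  if (any(valid)) {
    s <- seeds[valid, , drop = FALSE]
    d0 <- lk$dir[valid, , drop = FALSE]
    fwd <- propagate_half(s, d0, lookup, params)
    bwd <- propagate_half(s, -d0, lookup, params)
    streamlines <- lapply(seq_len(nrow(s)), function(i) {
      b <- bwd[[i]]
      rbind(b[rev(seq_len(nrow(b))), , drop = FALSE], s[i, , drop = FALSE],
            fwd[[i]])
    })
  }
  lens <- vapply(streamlines, function(m) (nrow(m) - 1) * params$step, 0)
  too_short <- lens < params$min_length
  too_long <- lens > params$max_length
  keep <- !too_short & !too_long
  list(streamlines = streamlines[keep], lengths = lens[keep],
       n_seeds = nrow(seeds), n_rejected_seed = n_rejected_seed,
       n_short = sum(too_short), n_long = sum(too_long))
}

#' Track a single streamline from a seed point
#'
#' Bidirectional Euler (or RK4) integration along the sign-coherent principal
#' eigenvector with a fixed step; terminates on FA below `fa_stop`, turning
#' angle above `max_angle`, or leaving the grid. The two half-tracks are
#' concatenated at the seed.
#'
#' @param tf a `tensor_field`.
#' @param fa the matching FA `volume3d` (from [compute_fa()]).
#' @param seed_point world-mm position, length 3.
#' @param params a [tracking_params()].
#' @return list with `points` (n x 3 world mm), `length` (mm) and `status`
#'   (`"retained"`, `"rejected_seed"`, `"too_short"`, or `"too_long"`).
#' @export
track_streamline <- function(tf, fa, seed_point, params = tracking_params()) {
  res <- track_from_seeds(tf, fa, matrix(seed_point, 1, 3), params)
  if (res$n_rejected_seed > 0)
    return(list(points = NULL, length = NA_real_, status = "rejected_seed"))
  if (length(res$streamlines))
    return(list(points = res$streamlines[[1]], length = res$lengths[1],
                status = "retained"))
  list(points = NULL, length = NA_real_,
       status = if (res$n_long > 0) "too_long" else "too_short")
}

#' Track a fiber bundle from a seed region
#'
#' Draws `seeds_per_voxel` uniformly jittered seed points inside each
#' seed-region voxel (the only randomness; fully reproducible under
#' `params$rng_seed`) and integrates every seed bidirectionally. Seeds in
#' sub-threshold FA are counted as rejected, not errors.
#'
#' @inheritParams track_streamline
#' @param seed_mask logical 3-D array on the tensor grid (non-empty).
#' @return list of class `fiber_bundle`: `streamlines` (list of n x 3 world-mm
#'   matrices), `lengths`, `step`, seed bookkeeping counts, and the params.
#' @export
track_bundle <- function(tf, fa, seed_mask, params = tracking_params()) {
  if (!any(seed_mask)) stop("seed region is empty")
  ijk <- which(seed_mask, arr.ind = TRUE)
  centres <- voxel_to_world(list(affine = tf$affine), ijk)
  seeds <- withr::with_seed(params$rng_seed, {
    rep_c <- centres[rep(seq_len(nrow(centres)), each = params$seeds_per_voxel), ,
                     drop = FALSE]
    jit <- matrix(stats::runif(length(rep_c), -0.5, 0.5), ncol = 3)
    rep_c + jit %*% diag(tf$spacing)
  })
  res <- track_from_seeds(tf, fa, seeds, params)
  structure(c(res, list(step = params$step, params = params)),
            class = "fiber_bundle")
}

#' @export
print.fiber_bundle <- function(x, ...) {
  cat(sprintf("<fiber_bundle> %d retained fibers of %d seeds (%d sub-threshold, %d short, %d long)\n",
              length(x$streamlines), x$n_seeds, x$n_rejected_seed, x$n_short,
              x$n_long))
  if (length(x$lengths))
    cat(sprintf("  length: mean %.1f mm, range [%.1f, %.1f]\n",
                mean(x$lengths), min(x$lengths), max(x$lengths)))
  invisible(x)
}

#' Write a bundle as JSON lines
#'
#' One JSON object per streamline (`{"id": i, "points": [[x,y,z], ...]}`), a
#' plain-text interchange format convenient for testing and external viewers.
#'
#' @param bundle a `fiber_bundle`.
#' @param path output file.
#' @export
write_bundle_jsonl <- function(bundle, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(bundle$streamlines)) {
    writeLines(jsonlite::toJSON(list(id = i,
                                     points = unname(bundle$streamlines[[i]])),
                                auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}
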