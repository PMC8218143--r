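# Shared fixtures: all built in code at test time.

# Miniature phantom spec for fast unit tests (16 x 16 x 12 at 2 mm).
tiny_spec <- function(...) {
  phantom_spec(grid_shape = c(16, 16, 12), spacing = 2,
               lesion_center = c(-10, 0, 0), lesion_radius = 5,
               n_directions = 12, ...)
}

# Uniform tensor slab: principal direction `dir`, eigenvalues `lam`, on an
# nx x ny x nz grid at `spacing` mm with a centred affine.
uniform_tensor_field <- function(dims = c(40, 20, 20), spacing = 1,
                                 dir = c(1, 0, 0),
                                 lam = c(1.7, 0.3, 0.3) * 1e-3) {
  dir <- dir / sqrt(sum(dir^2))
  nv <- prod(dims)
  dl <- lam[1] - lam[2]
  lower <- array(0, c(dims, 6))
  lower[, , , 1] <- lam[2] + dl * dir[1]^2
  lower[, , , 2] <- lam[2] + dl * dir[2]^2
  lower[, , , 3] <- lam[2] + dl * dir[3]^2
  lower[, , , 4] <- dl * dir[1] * dir[2]
  lower[, , , 5] <- dl * dir[1] * dir[3]
  lower[, , , 6] <- dl * dir[2] * dir[3]
  tensor_field(lower, array(TRUE, dims), spacing = rep(spacing, 3))
}

# Circular (in-plane) direction field: tangents of circles about the origin
# in the x-y plane, anisotropic only in the x >= 0 half-space so that tracks
# terminate at the half-plane boundary instead of looping. Used for
# curvature checks against analytic arc lengths.
circular_tensor_field <- function(dims = c(60, 60, 8), spacing = 1,
                                  lam = c(1.7, 0.3, 0.3) * 1e-3) {
  geo <- volume3d(array(0, dims), rep(spacing, 3))
  grid <- as.matrix(expand.grid(i = seq_len(dims[1]), j = seq_len(dims[2]),
                                k = seq_len(dims[3])))
  w <- voxel_to_world(geo, grid)
  tx <- -w[, 2]; ty <- w[, 1]
  nrm <- sqrt(tx^2 + ty^2); nrm[nrm == 0] <- 1
  e1 <- cbind(tx / nrm, ty / nrm, 0)
  dl <- (lam[1] - lam[2]) * (w[, 1] >= 0)   # isotropic (FA 0) for x < 0
  lower <- array(0, c(dims, 6))
  lower[, , , 1] <- array(lam[2] + dl * e1[, 1]^2, dims)
  lower[, , , 2] <- array(lam[2] + dl * e1[, 2]^2, dims)
  lower[, , , 3] <- lam[2]
  lower[, , , 4] <- array(dl * e1[, 1] * e1[, 2], dims)
  tensor_field(lower, array(TRUE, dims), spacing = rep(spacing, 3))
}

# Noise-free DWI signals from a single tensor, for fit round-trips.
signals_from_tensor <- function(D, gtab, s0 = 1000) {
  sapply(seq_len(gtab$n), function(i) {
    g <- gtab$bvecs[i, ]
    s0 * exp(-gtab$bvals[i] * drop(t(g) %*% D %*% g))
  })
}

simple_gtab <- function(n_dir = 12, bval = 1000) {
  i <- seq_len(n_dir) - 1
  z <- (2 * i + 1) / n_dir - 1
  phi <- i * pi * (3 - sqrt(5))
  r <- sqrt(pmax(1 - z^2, 0))
  gradient_table(c(0, rep(bval, n_dir)),
                 rbind(c(0, 0, 0), cbind(r * cos(phi), r * sin(phi), z)))
}

# Independent brute-force labelling oracle: repeated full-scan flood fill
# growing one component at a time by neighbourhood dilation.
brute_force_components <- function(mask, connectivity) {
  d <- dim(mask)
  offs <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  ord <- rowSums(abs(offs))
  offs <- offs[switch(as.character(connectivity),
                      "6" = ord == 1, "18" = ord >= 1 & ord <= 2,
                      "26" = ord >= 1), , drop = FALSE]
  labels <- array(0L, d)
  lab <- 0L
  idx_all <- which(mask, arr.ind = TRUE)
  adjacent <- function(a, b) {
    dd <- abs(a - b)
    any(apply(offs, 1, function(o) all(dd == abs(o)))) && !all(dd == 0)
  }
  for (r in seq_len(nrow(idx_all))) {
    v <- idx_all[r, ]
    if (labels[v[1], v[2], v[3]] > 0L) next
    lab <- lab + 1L
    comp <- matrix(v, 1, 3)
    labels[v[1], v[2], v[3]] <- lab
    repeat {
      grew <- FALSE
      for (r2 in seq_len(nrow(idx_all))) {
        u <- idx_all[r2, ]
        if (labels[u[1], u[2], u[3]] > 0L) next
        for (r3 in seq_len(nrow(comp))) {
          if (adjacent(u, comp[r3, ])) {
            labels[u[1], u[2], u[3]] <- lab
            comp <- rbind(comp, u)
            grew <- TRUE
            break
          }
        }
      }
      if (!grew) break
    }
  }
  labels
}

# Exact Wilcoxon two-sided p by explicit enumeration of all 2^n sign
# assignments (independent oracle for n <= 12).
brute_force_wilcoxon_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  ws <- signs %*% r
  p_le <- mean(ws <= w_obs + 1e-12)
  p_ge <- mean(ws >= w_obs - 1e-12)
  min(1, 2 * min(p_le, p_ge))
}
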