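# Diffusion tensor estimation and scalar maps.
#
# The single-tensor model is S_i = S0 * exp(-b_i g_i' D g_i). With
# theta = (log S0, Dxx, Dyy, Dzz, Dxy, Dxz, Dyz) the log-signal is linear,
# log S = B theta, where row i of the design matrix B is
# [1, -b gx^2, -b gy^2, -b gz^2, -2b gx gy, -2b gx gz, -2b gy gz].

tensor_design_matrix <- function(gtab) {
  g <- gtab$bvecs
  b <- gtab$bvals
  cbind(1,
        -b * g[, 1]^2, -b * g[, 2]^2, -b * g[, 3]^2,
        -2 * b * g[, 1] * g[, 2],
        -2 * b * g[, 1] * g[, 3],
        -2 * b * g[, 2] * g[, 3])
}

# Eigen-decomposition of the 6-component lower-triangular tensors in `lower`
# (V x 6, order Dxx Dyy Dzz Dxy Dxz Dyz). Returns eigenvalues sorted
# descending and the principal eigenvector.
tensor_eigensystem <- function(lower) {
  v <- nrow(lower)
  evals <- matrix(0, v, 3)
  e1 <- matrix(0, v, 3)
  # isotropic fast path: diagonal tensors with equal entries need no solver
  iso <- lower[, 4] == 0 & lower[, 5] == 0 & lower[, 6] == 0 &
    lower[, 1] == lower[, 2] & lower[, 2] == lower[, 3]
  if (any(iso)) {
    evals[iso, ] <- lower[iso, 1]
    e1[iso, 1] <- 1
  }
  for (i in which(!iso)) {
    m <- matrix(c(lower[i, 1], lower[i, 4], lower[i, 5],
                  lower[i, 4], lower[i, 2], lower[i, 6],
                  lower[i, 5], lower[i, 6], lower[i, 3]), 3, 3)
    es <- eigen(m, symmetric = TRUE)
    evals[i, ] <- es$values
    e1[i, ] <- es$vectors[, 1]
  }
  list(evals = evals, e1 = e1)
}

new_tensor_field <- function(dims, lower, s0, mask, spacing, affine, method) {
  es <- tensor_eigensystem(lower)
  la <- array(0, c(dims, 3)); e1a <- array(0, c(dims, 3))
  lo <- array(0, c(dims, 6)); s0a <- array(0, dims)
  idx <- which(mask)
  for (j in 1:3) {
    sl <- array(0, dims); sl[idx] <- es$evals[, j]; la[, , , j] <- sl
    sl <- array(0, dims); sl[idx] <- es$e1[, j]; e1a[, , , j] <- sl
  }
  for (j in 1:6) {
    sl <- array(0, dims); sl[idx] <- lower[, j]; lo[, , , j] <- sl
  }
  s0a[idx] <- s0
  structure(list(lower = lo, s0 = s0a, evals = la, e1 = e1a, mask = mask,
                 n_negative_evals = sum(es$evals < 0),
                 spacing = spacing, affine = affine, method = method),
            class = "tensor_field")
}

#' Build a tensor field from per-voxel tensor components
#'
#' Used for ground-truth phantom fields and for constructing analytic test
#' fields; [fit_tensor()] produces the same structure from data.
#'
#' @param lower 4-D array `c(dims, 6)` of tensor components in the order
#'   Dxx, Dyy, Dzz, Dxy, Dxz, Dyz (mm^2/s).
#' @param mask logical 3-D array of voxels carrying a tensor.
#' @param s0 optional 3-D array of non-diffusion-weighted signal.
#' @param spacing,affine grid geometry as in [volume3d()].
#' @return object of class `tensor_field` with per-voxel eigenvalues
#'   (descending) and principal eigenvector populated.
#' @export
tensor_field <- function(lower, mask, s0 = NULL, spacing = c(1, 1, 1),
                         affine = NULL) {
  dims <- dim(lower)[1:3]
  geo <- volume3d(array(0, dims), spacing, affine)
  idx <- which(mask)
  lw <- matrix(0, length(idx), 6)
  for (j in 1:6) lw[, j] <- lower[, , , j][idx]
  s0v <- if (is.null(s0)) rep(1, length(idx)) else s0[idx]
  new_tensor_field(dims, lw, s0v, mask, geo$spacing, geo$affine, "analytic")
}

#' @export
print.tensor_field <- function(x, ...) {
  d <- dim(x$mask)
  cat(sprintf("<tensor_field> %d x %d x %d grid, %d fitted voxels (%s), %d negative eigenvalues\n",
              d[1], d[2], d[3], sum(x$mask), x$method, x$n_negative_evals))
  invisible(x)
}

#' Fit the diffusion tensor voxel-wise
#'
#' `linear_ls` solves the log-linearized system by ordinary least squares;
#' voxels containing non-positive signals have those measurements excluded
#' from their fit. `nonlinear_ls` (the default, matching standard practice)
#' refines the linear solution by damped Gauss-Newton least squares on the
#' exponential model itself, which removes the log-transform's noise
#' weighting bias. Both are exact inverses on noise-free data.
#'
#' @param dwi a [dwi_dataset()].
#' @param mask logical 3-D array of voxels to fit (default: voxels whose mean
#'   b = 0 signal is positive).
#' @param method `"nonlinear_ls"` or `"linear_ls"`.
#' @param max_iter,tol Gauss-Newton iteration cap and relative-change
#'   stopping tolerance.
#' @return a `tensor_field` (see [tensor_field()]).
#' @export
fit_tensor <- function(dwi, mask = NULL, method = c("nonlinear_ls", "linear_ls"),
                       max_iter = 30L, tol = 1e-10) {
  method <- match.arg(method)
  stopifnot(inherits(dwi, "dwi_dataset"))
  gtab <- dwi$gtab
  dims <- dim(dwi$data)[1:3]
  n <- gtab$n
  sig <- matrix(dwi$data, prod(dims), n)
  if (is.null(mask)) {
    s0m <- rowMeans(sig[, gtab$b0, drop = FALSE])
    mask <- array(s0m > 0, dims)
  }
  idx <- which(mask)
  if (!length(idx)) stop("tensor mask is empty")
  S <- t(sig[idx, , drop = FALSE])              # n x V
  B <- tensor_design_matrix(gtab)
  if (qr(B)$rank < 7L)
    stop("singular tensor design matrix: directions do not span 6 unique orientations")
  V <- ncol(S)

  # --- log-linear fit -------------------------------------------------------
  pos <- S > 0
  allpos <- colSums(pos) == n
  theta <- matrix(0, 7, V)
  L <- log(pmax(S, .Machine$double.xmin))
  BtBinvBt <- solve(crossprod(B), t(B))
  theta[, allpos] <- BtBinvBt %*% L[, allpos, drop = FALSE]
  if (any(!allpos)) {
    for (v in which(!allpos)) {
      keep <- pos[, v]
      if (sum(keep) < 7L) { theta[, v] <- c(log(max(mean(S[, v]), 1e-12)), rep(0, 6)); next }
      Bk <- B[keep, , drop = FALSE]
      if (qr(Bk)$rank < 7L) { theta[, v] <- c(log(max(mean(S[keep, v]), 1e-12)), rep(0, 6)); next }
      theta[, v] <- solve(crossprod(Bk), crossprod(Bk, L[keep, v]))
    }
  }

  # --- Gauss-Newton refinement on the exponential model --------------------
  if (method == "nonlinear_ls") {
    O <- matrix(0, n, 49)                       # row i = vec(B_i B_i')
    for (i in seq_len(n)) O[i, ] <- as.vector(tcrossprod(B[i, ]))
    pred <- exp(B %*% theta)                    # n x V
    sse <- colSums((S - pred)^2)
    lambda <- rep(1e-6, V)
    for (it in seq_len(max_iter)) {
      W2 <- t(pred^2)                           # V x n
      M <- W2 %*% O                             # V x 49
      R <- t(pred * (S - pred)) %*% B           # V x 7  (J' r)
      delta <- matrix(0, 7, V)
      for (v in seq_len(V)) {
        A <- matrix(M[v, ], 7, 7)
        diag(A) <- diag(A) * (1 + lambda[v]) + 1e-300
        dv <- tryCatch(solve(A, R[v, ]), error = function(e) rep(0, 7))
        delta[, v] <- dv
      }
      cand <- theta + delta
      pred_c <- exp(B %*% cand)
      sse_c <- colSums((S - pred_c)^2)
      better <- sse_c <= sse + 1e-300
      theta[, better] <- cand[, better]
      pred[, better] <- pred_c[, better]
      lambda[better] <- pmax(lambda[better] / 4, 1e-10)
      lambda[!better] <- lambda[!better] * 10
      moved <- max(abs(delta[, better, drop = FALSE]))
      sse[better] <- sse_c[better]
      if (!any(better) || (length(moved) && is.finite(moved) &&
                           moved < tol * max(1, max(abs(theta)))))
        break
    }
  }

  new_tensor_field(dims, t(theta[2:7, , drop = FALSE]), exp(theta[1, ]),
                   mask, dwi$spacing, dwi$affine, method)
}

#' Fractional anisotropy map
#'
#' FA = sqrt(3/2) * sqrt(sum((lambda_i - lambda_bar)^2)) / sqrt(sum(lambda_i^2)),
#' in `[0, 1]`. Negative eigenvalues (possible in noisy fits) are clamped to 0
#' for the scalar map; the number of clamped voxels is recorded in the
#' `n_clamped` attribute. FA is defined as 0 where all eigenvalues are 0.
#'
#' @param tf a `tensor_field`.
#' @return `volume3d` of FA (0 outside the fitted mask).
#' @export
compute_fa <- function(tf) {
  l1 <- tf$evals[, , , 1]; l2 <- tf$evals[, , , 2]; l3 <- tf$evals[, , , 3]
  n_clamped <- sum((l1 < 0 | l2 < 0 | l3 < 0) & tf$mask)
  l1 <- pmax(l1, 0); l2 <- pmax(l2, 0); l3 <- pmax(l3, 0)
  lb <- (l1 + l2 + l3) / 3
  num <- sqrt((l1 - lb)^2 + (l2 - lb)^2 + (l3 - lb)^2)
  den <- sqrt(l1^2 + l2^2 + l3^2)
  fa <- ifelse(den > 0, sqrt(1.5) * num / den, 0)
  fa[!tf$mask] <- 0
  out <- volume3d(array(fa, dim(tf$mask)), tf$spacing, tf$affine)
  attr(out, "n_clamped") <- n_clamped
  out
}

#' Mean diffusivity map
#'
#' @param tf a `tensor_field`.
#' @return `volume3d` of (lambda1 + lambda2 + lambda3) / 3, mm^2/s.
#' @export
compute_md <- function(tf) {
  md <- (tf$evals[, , , 1] + tf$evals[, , , 2] + tf$evals[, , , 3]) / 3
  md[!tf$mask] <- 0
  volume3d(array(md, dim(tf$mask)), tf$spacing, tf$affine)
}

#' Closed-form FA of an eigenvalue triple
#'
#' Convenience scalar form of the FA formula, used for ground-truth checks.
#'
#' @param lambdas numeric length-3 eigenvalues.
#' @return FA in `[0, 1]`.
#' @export
fa_from_eigenvalues <- function(lambdas) {
  l <- pmax(as.numeric(lambdas), 0)
  if (all(l == 0)) return(0)
  lb <- mean(l)
  sqrt(1.5) * sqrt(sum((l - lb)^2)) / sqrt(sum(l^2))
}
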