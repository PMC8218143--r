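#' Diffusion gradient table
#'
#' Parses FSL-style b-value / b-vector text (bvals: one row of N values;
#' bvecs: 3 rows x N columns) into a validated gradient table. Direction
#' vectors whose norm deviates from 1 by less than 1e-3 are renormalized;
#' larger deviations are rejected. Tensor fitting requires at least one b = 0
#' measurement and at least 6 unique non-collinear directions (uniqueness is
#' assessed up to sign, since diffusion is antipodally symmetric).
#'
#' @param bvals path to a bval file, or a numeric vector of b-values
#'   (s/mm^2).
#' @param bvecs path to a bvec file, or a 3 x N (or N x 3) numeric matrix of
#'   direction vectors.
#' @param b0_threshold b-values at or below this count as b = 0 (default 0).
#' @return list of class `gradient_table` with `bvals`, `bvecs` (N x 3, unit
#'   rows or zero rows), `n`, `b0` (logical), `n_unique_dirs`.
#' @export
gradient_table <- function(bvals, bvecs, b0_threshold = 0) {
  if (is.character(bvals))
    bvals <- scan(bvals, what = numeric(), quiet = TRUE)
  bvals <- as.numeric(bvals)
  if (is.character(bvecs)) {
    rows <- utils::read.table(bvecs)
    bvecs <- as.matrix(rows)
  }
  bvecs <- as.matrix(bvecs)
  if (nrow(bvecs) == 3L && ncol(bvecs) != 3L) bvecs <- t(bvecs)
  if (ncol(bvecs) != 3L)
    stop("`bvecs` must be 3 x N (FSL layout) or N x 3")
  if (nrow(bvecs) != length(bvals))
    stop("gradient table length mismatch: ", length(bvals), " b-values vs ",
         nrow(bvecs), " direction vectors")
  if (any(!is.finite(bvals)) || any(bvals < 0))
    stop("b-values must be finite and >= 0")
  b0 <- bvals <= b0_threshold
  nrm <- sqrt(rowSums(bvecs^2))
  bad <- !b0 & abs(nrm - 1) >= 1e-3
  if (any(bad))
    stop("b-vector rows ", paste(which(bad), collapse = ", "),
         " have norm outside 1 +/- 1e-3 and cannot be renormalized")
  zero_dw <- !b0 & nrm == 0
  if (any(zero_dw))
    stop("diffusion-weighted rows ", paste(which(zero_dw), collapse = ", "),
         " have zero direction vectors")
  bvecs[!b0, ] <- bvecs[!b0, , drop = FALSE] / nrm[!b0]
  bvecs[b0, ] <- 0
  dimnames(bvecs) <- NULL
  bvals <- unname(bvals)
  if (!any(b0)) stop("gradient table has no b = 0 measurement")
  dirs <- bvecs[!b0, , drop = FALSE]
  # canonical sign, then round: unique up to antipodal flip
  flip <- dirs[, 1] < 0 | (dirs[, 1] == 0 & dirs[, 2] < 0) |
    (dirs[, 1] == 0 & dirs[, 2] == 0 & dirs[, 3] < 0)
  dirs[flip, ] <- -dirs[flip, , drop = FALSE]
  n_unique <- nrow(unique(round(dirs, 6)))
  if (n_unique < 6L)
    stop("tensor fitting needs >= 6 unique diffusion directions, found ",
         n_unique)
  structure(list(bvals = bvals, bvecs = bvecs, n = length(bvals),
                 b0 = b0, n_unique_dirs = n_unique),
            class = "gradient_table")
}

#' @export
print.gradient_table <- function(x, ...) {
  cat(sprintf("<gradient_table> %d volumes: %d b=0, %d DW (b in [%g, %g]), %d unique directions\n",
              x$n, sum(x$b0), sum(!x$b0), min(x$bvals[!x$b0]),
              max(x$bvals[!x$b0]), x$n_unique_dirs))
  invisible(x)
}

#' Write a gradient table in FSL layout
#'
#' @param gtab a [gradient_table()].
#' @param bval_path,bvec_path output text files.
#' @export
write_gradient_table <- function(gtab, bval_path, bvec_path) {
  num <- function(x) formatC(x, format = "g", digits = 17)
  writeLines(paste(num(gtab$bvals), collapse = " "), bval_path)
  m <- t(gtab$bvecs)
  writeLines(apply(m, 1, function(r) paste(num(r), collapse = " ")), bvec_path)
  invisible(NULL)
}

#' 4-D diffusion-weighted dataset
#'
#' @param data 4-D array (x, y, z, volume).
#' @param gtab a [gradient_table()] whose length matches `dim(data)[4]`.
#' @param spacing,affine grid geometry as in [volume3d()].
#' @return list of class `dwi_dataset`.
#' @export
dwi_dataset <- function(data, gtab, spacing = c(1, 1, 1), affine = NULL) {
  stopifnot(length(dim(data)) == 4L, inherits(gtab, "gradient_table"))
  if (dim(data)[4] != gtab$n)
    stop("4th dimension (", dim(data)[4], ") does not match gradient table (",
         gtab$n, ")")
  geo <- volume3d(array(0, dim(data)[1:3]), spacing, affine)
  structure(list(data = data, gtab = gtab, spacing = geo$spacing,
                 affine = geo$affine),
            class = "dwi_dataset")
}

#' @export
print.dwi_dataset <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<dwi_dataset> %d x %d x %d voxels x %d volumes, spacing %s mm\n",
              d[1], d[2], d[3], d[4],
              paste(signif(x$spacing, 4), collapse = " x ")))
  invisible(x)
}
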