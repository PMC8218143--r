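test_that("sagittal flip reflects world coordinates and is an involution", {
  v <- volume3d(array(0, c(9, 8, 6)), spacing = c(2, 2, 2))
  # single voxel at world x = midline + 4 mm lands at midline - 4 mm
  axis_x <- voxel_to_world(v, cbind(1:9, 1, 1))[, 1]
  ijk <- which(abs(axis_x - 4) < 1e-9)
  v$data[ijk, 4, 3] <- 7
  f <- flip_sagittal(v, 0)
  ijk_m <- which(abs(axis_x + 4) < 1e-9)
  expect_equal(f$data[ijk_m, 4, 3], 7)
  expect_equal(sum(f$data != 0), 1L)
  # involution is exact on the grid-aligned midline
  expect_identical(flip_sagittal(f, 0)$data, v$data)
})

test_that("flip leaves mirror-symmetric volumes unchanged and rejects bad midlines", {
  set.seed(1)
  half <- array(runif(5 * 6 * 4), c(5, 6, 4))
  sym <- array(0, c(10, 6, 4))
  sym[1:5, , ] <- half
  sym[10:6, , ] <- half
  v <- volume3d(sym, spacing = c(1, 1, 1))
  expect_equal(flip_sagittal(v)$data, v$data)
  expect_error(flip_sagittal(v, 100), "midline")
})

test_that("flip at a non-aligned midline resamples by interpolation", {
  v <- volume3d(array(rep(1:10, 12), c(10, 4, 3)), spacing = c(1, 1, 1))
  f <- flip_sagittal(v, 0.25)  # half-voxel offset: interpolated
  # linear ramp in x stays a ramp after reflection about x = 0.25
  x <- voxel_to_world(v, cbind(1:10, 1, 1))[, 1]
  keep <- !is.na(f$data[, 1, 1])
  expect_equal(f$data[keep, 1, 1],
               approx(x, v$data[, 1, 1], xout = 2 * 0.25 - x[keep])$y)
})

test_that("symmetric template is the flip mean and a flip fixed point", {
  set.seed(2)
  v <- volume3d(array(runif(8 * 6 * 4, 1, 2), c(8, 6, 4)), spacing = c(2, 1, 1))
  s <- make_symmetric_template(v)
  expect_equal(s$data, (v$data + flip_sagittal(v)$data) / 2)
  expect_equal(flip_sagittal(s)$data, s$data)
  # mirrored pair (10, 2) averages to 6 on both sides
  w <- volume3d(array(0, c(4, 3, 3)), spacing = c(1, 1, 1))
  w$data[1, 2, 2] <- 10
  w$data[4, 2, 2] <- 2
  s2 <- make_symmetric_template(w)
  expect_equal(s2$data[1, 2, 2], 6)
  expect_equal(s2$data[4, 2, 2], 6)
})

test_that("gaussian smoothing preserves mass, fixes constants, and is identity at fwhm 0", {
  v <- volume3d(array(0, c(20, 20, 20)), spacing = c(2, 2, 2))
  v$data[10, 10, 10] <- 100
  s <- gaussian_smooth(v, 4)
  expect_lt(abs(sum(s$data) - 100) / 100, 0.001)
  expect_lt(max(s$data), 100)
  cv <- volume3d(array(3.5, c(6, 6, 6)), spacing = c(1, 2, 3))
  expect_equal(gaussian_smooth(cv, 5)$data, cv$data, tolerance = 1e-12)
  expect_identical(gaussian_smooth(v, 0)$data, v$data)
  expect_error(gaussian_smooth(v, -1), "fwhm")
})

test_that("connected components match a brute-force oracle on random masks", {
  set.seed(33)
  for (conn in c(6L, 18L, 26L)) {
    for (rep in 1:3) {
      mask <- array(runif(10 * 9 * 8) < 0.25, c(10, 9, 8))
      got <- connected_components(mask, conn)
      want <- brute_force_components(mask, conn)
      # same partition: labels must be a relabelling of each other
      expect_equal(max(want), got$n)
      if (got$n > 0) {
        tab <- table(got$labels[mask], want[mask])
        expect_true(all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1))
        expect_equal(sort(got$sizes, decreasing = TRUE), got$sizes)
      }
    }
  }
})

test_that("connectivity conventions distinguish diagonal touching", {
  m <- array(FALSE, c(4, 4, 4))
  m[1, 1, 1] <- TRUE
  m[2, 2, 2] <- TRUE
  expect_equal(connected_components(m, 26)$n, 1L)
  expect_equal(connected_components(m, 6)$n, 2L)
  m2 <- array(FALSE, c(4, 4, 4))
  m2[1, 1, 1] <- TRUE; m2[1, 2, 2] <- TRUE   # face-diagonal within a plane
  expect_equal(connected_components(m2, 18)$n, 1L)
  expect_equal(connected_components(m2, 6)$n, 2L)
  expect_equal(connected_components(array(FALSE, c(3, 3, 3)))$n, 0L)
})

test_that("component ordering is by size then smallest linear index", {
  m <- array(FALSE, c(10, 3, 3))
  m[1:2, 1, 1] <- TRUE          # 2 voxels, earliest index
  m[5:8, 1, 1] <- TRUE          # 4 voxels
  m[10, 1, 1] <- TRUE           # 1 voxel
  cc <- connected_components(m, 6)
  expect_equal(cc$sizes, c(4L, 2L, 1L))
  expect_equal(unique(cc$labels[5:8, 1, 1]), 1L)
  expect_equal(unique(cc$labels[1:2, 1, 1]), 2L)
})

test_that("resampling halves spacing into doubled grids and preserves content location", {
  set.seed(4)
  v <- volume3d(array(runif(8 * 8 * 8), c(8, 8, 8)), spacing = c(2, 2, 2))
  r <- resample(v, 1)
  expect_equal(dim(r$data), c(16L, 16L, 16L))
  expect_equal(r$spacing, c(1, 1, 1))
  # identity at the same spacing; constants stay constant
  expect_identical(resample(v, 2)$data, v$data)
  cv <- volume3d(array(2.5, c(6, 6, 6)), spacing = c(2, 2, 2))
  rc <- resample(cv, 1.3)
  expect_equal(range(rc$data, na.rm = TRUE), c(2.5, 2.5))
  expect_error(resample(v, 0), "target_spacing")
  # world coordinates of a hot voxel are preserved
  v2 <- volume3d(array(0, c(8, 8, 8)), spacing = c(2, 2, 2))
  v2$data[3, 4, 5] <- 1
  w_hot <- voxel_to_world(v2, cbind(3, 4, 5))
  r2 <- resample(v2, 1)
  peak <- which(r2$data == max(r2$data, na.rm = TRUE), arr.ind = TRUE)
  expect_lt(max(abs(voxel_to_world(r2, peak[1, , drop = FALSE]) - w_hot)), 1)
})

test_that("volumes survive a NIfTI round trip with geometry intact", {
  set.seed(5)
  v <- volume3d(array(rnorm(6 * 5 * 4), c(6, 5, 4)), spacing = c(2, 2.5, 3))
  path <- tempfile(fileext = ".nii.gz")
  write_volume(v, path)
  r <- read_volume(path)
  expect_equal(r$data, v$data, tolerance = 1e-7)
  expect_equal(r$spacing, v$spacing, tolerance = 1e-6)
  expect_equal(r$affine, v$affine, tolerance = 1e-5)
  # masks round-trip as 0/1 uint8
  m <- volume3d(array(c(TRUE, FALSE), c(6, 5, 4)), v$spacing, v$affine)
  write_mask(m, path)
  expect_equal(read_volume(path)$data, array(as.numeric(m$data), dim(m$data)))
})

test_that("trilinear sampling interpolates linear fields exactly", {
  v <- volume3d(array(0, c(8, 8, 8)), spacing = c(1, 1, 1))
  grid <- as.matrix(expand.grid(i = 1:8, j = 1:8, k = 1:8))
  w <- voxel_to_world(v, grid)
  v$data[] <- 2 * w[, 1] - 3 * w[, 2] + 0.5 * w[, 3]
  set.seed(6)
  pts <- cbind(runif(50, -2, 2), runif(50, -2, 2), runif(50, -2, 2))
  expect_equal(sample_trilinear(v, pts),
               2 * pts[, 1] - 3 * pts[, 2] + 0.5 * pts[, 3], tolerance = 1e-10)
  expect_true(is.na(sample_trilinear(v, cbind(100, 0, 0))))
})
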