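test_that("SUV map follows activity * weight / dose with linearity in dose", {
  v <- volume3d(array(10000, c(4, 4, 4)), spacing = c(2, 2, 2))
  p <- suv_params(body_weight = 70000, injected_dose = 1.9e8)
  suv <- compute_suv(v, p)
  expect_equal(suv$data[1, 1, 1], 3.684, tolerance = 5e-4)
  zero <- compute_suv(volume3d(array(0, c(4, 4, 4)), c(2, 2, 2)), p)
  expect_equal(max(abs(zero$data)), 0)
  p2 <- suv_params(70000, 2 * 1.9e8)
  expect_equal(compute_suv(v, p2)$data, suv$data / 2)
  expect_error(suv_params(0, 1e8), "body_weight")
  expect_error(suv_params(70000, -1), "injected_dose")
})

test_that("GM mask uses an inclusive threshold", {
  gm <- volume3d(array(c(0.29, 0.30, 0.31, 0), c(4, 2, 2)), c(1, 1, 1))
  m <- apply_gm_mask(gm, 0.30)
  expect_equal(m[1:4, 1, 1], c(FALSE, TRUE, TRUE, FALSE))
  expect_false(any(apply_gm_mask(volume3d(array(0, c(2, 2, 2)), c(1, 1, 1)), 0.3)))
  expect_true(all(apply_gm_mask(gm, 0)))
  expect_error(apply_gm_mask(gm, 1.5), "threshold")
})

test_that("cerebellar normalization scales to unit reference mean and is scale invariant", {
  d <- c(6, 6, 6)
  suv <- volume3d(array(seq(1, 4, length.out = prod(d)), d), c(2, 2, 2))
  gm <- array(TRUE, d)
  cereb <- array(FALSE, d); cereb[, , 1] <- TRUE
  r <- normalize_cerebellum(suv, gm, cereb)
  expect_equal(mean(r$data[cereb & gm]), 1)
  r2 <- normalize_cerebellum(volume3d(suv$data * 5.7, suv$spacing, suv$affine),
                             gm, cereb)
  expect_equal(r2$data, r$data)
  # uniform volume -> SUVr identically 1; ratio 3/2 = 1.5 spot check
  u <- volume3d(array(2, d), c(2, 2, 2))
  expect_equal(range(normalize_cerebellum(u, gm, cereb)$data), c(1, 1))
  expect_error(normalize_cerebellum(suv, gm, array(FALSE, d)), "empty")
})

test_that("AI map implements the normalized flip difference with antisymmetry", {
  d <- c(8, 6, 4)
  suvr <- volume3d(array(1, d), c(2, 2, 2))
  suvr$data[2, 3, 2] <- 1.2
  suvr$data[7, 3, 2] <- 0.8   # mirror voxel under the centred affine
  ai <- compute_ai(suvr)
  expect_equal(ai$data[2, 3, 2], (1.2 - 0.8) / (2 * (1.2 + 0.8)) * 100)
  expect_equal(ai$data[2, 3, 2], 10)
  expect_equal(ai$data[7, 3, 2], -10)
  # I = fI everywhere -> AI identically zero
  sym <- volume3d(array(2, d), c(2, 2, 2))
  expect_equal(range(compute_ai(sym)$data), c(0, 0))
  # full antisymmetry on a random positive image
  set.seed(7)
  rnd <- volume3d(array(runif(prod(d), 0.5, 2), d), c(2, 2, 2))
  arnd <- compute_ai(rnd)$data
  expect_equal(arnd, -arnd[d[1]:1, , ], tolerance = 1e-12)
  # zero-sum voxels are flagged undefined, not infinite
  z <- volume3d(array(1, d), c(2, 2, 2))
  z$data[3, 1, 1] <- 0; z$data[6, 1, 1] <- 0
  expect_true(is.na(compute_ai(z)$data[3, 1, 1]))
})

test_that("Z_AI standardizes GM asymmetry values", {
  d <- c(6, 2, 2)
  ai <- volume3d(array(0, d), c(1, 1, 1))
  gm <- array(FALSE, d)
  ai$data[1:3, 1, 1] <- c(-2, 0, 2)
  gm[1:3, 1, 1] <- TRUE
  z <- compute_zai(ai, gm)
  # population-sd convention: sd = sqrt(8/3), so X = 2 maps to +1.225
  expect_equal(z$data[3, 1, 1], 2 / sqrt(8 / 3), tolerance = 1e-12)
  expect_equal(round(z$data[3, 1, 1], 3), 1.225)
  expect_equal(z$data[2, 1, 1], 0)
  vals <- z$data[gm]
  expect_equal(mean(vals), 0, tolerance = 1e-12)
  expect_equal(sqrt(mean(vals^2)), 1, tolerance = 1e-12)
  # location invariance
  ai2 <- volume3d(ai$data + 5, ai$spacing, ai$affine)
  expect_equal(compute_zai(ai2, gm)$data[gm], z$data[gm], tolerance = 1e-12)
  # sample-sd convention differs by sqrt(n/(n-1))
  zs <- compute_zai(ai, gm, sd_type = "sample")
  expect_equal(zs$data[3, 1, 1], z$data[3, 1, 1] * sqrt(2 / 3), tolerance = 1e-12)
  # zero variance rejected with a diagnostic
  flat <- volume3d(array(1, d), c(1, 1, 1))
  expect_error(compute_zai(flat, array(TRUE, d)), "standard deviation")
})

test_that("the t-based asymmetry threshold reproduces the df-scaled critical values", {
  thr <- ai_threshold(n_subjects = 14)
  expect_equal(thr$df, 13)
  expect_equal(thr$critical_z_2dp, -1.77)
  expect_equal(ai_threshold(df = 1)$critical_z_2dp, -6.31)
  expect_equal(ai_threshold(df = 1e9)$critical_z, qnorm(0.05), tolerance = 1e-4)
  expect_error(ai_threshold(df = 0), "df")
  expect_error(ai_threshold(df = 5, alpha = 0.7), "alpha")
})

test_that("critical values agree with numerical t-quantile integration across df", {
  # independent oracle: solve P(T <= q) = alpha by integrating the t density
  t_quantile <- function(alpha, df) {
    cdf <- function(q) integrate(function(x) dt(x, df), -Inf, q,
                                 rel.tol = 1e-12)$value
    uniroot(function(q) cdf(q) - alpha, c(-500, 0), tol = 1e-10)$root
  }
  for (df in c(1, 2, 5, 13, 40, 200)) {
    expect_equal(ai_threshold(df = df)$critical_z, t_quantile(0.05, df),
                 tolerance = 1e-4)
  }
})

test_that("ROI extraction keeps the largest focal cluster and lateralizes it", {
  d <- c(12, 10, 8)
  z <- volume3d(array(0, d), c(2, 2, 2))
  gm <- array(TRUE, d)
  z$data[2:5, 2:5, 2:4] <- -3        # 48-voxel cluster, left of midline
  z$data[9:10, 7:8, 5:6] <- -3       # 8-voxel cluster
  roi <- extract_roi(z, gm, -1.77, min_voxels = 5)
  expect_true(roi$found)
  expect_equal(roi$voxel_count, 48L)
  expect_equal(roi$hemisphere, "left")
  expect_true(all(which(roi$mask, arr.ind = TRUE)[, 1] <= 5))
  # nothing suprathreshold -> clean empty status
  none <- extract_roi(volume3d(array(0, d), c(2, 2, 2)), gm, -1.77)
  expect_false(none$found)
  expect_match(none$status, "no significant hypometabolism")
  # clusters below the extent floor do not count as focal
  small <- volume3d(array(0, d), c(2, 2, 2))
  small$data[1:2, 1, 1] <- -5
  expect_false(extract_roi(small, gm, -1.77, min_voxels = 5)$found)
  expect_error(extract_roi(z, gm, 1.5), "critical_z")
})
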