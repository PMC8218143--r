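make_bundle <- function(streamlines, step = 1) {
  lens <- vapply(streamlines, function(m) (nrow(m) - 1) * step, 0)
  structure(list(streamlines = streamlines, lengths = lens, step = step,
                 n_seeds = length(streamlines), n_rejected_seed = 0L,
                 n_short = 0L, n_long = 0L),
            class = "fiber_bundle")
}

test_that("bundle metrics implement the four definitions", {
  # FA field: 0.4 for x < 0, 0.8 for x >= 0 on a fine grid with voxel
  # centres at integer coordinates
  d <- c(41, 11, 11)
  fa <- volume3d(array(0, d), spacing = c(1, 1, 1))
  grid <- as.matrix(expand.grid(i = 1:d[1], j = 1:d[2], k = 1:d[3]))
  w <- voxel_to_world(fa, grid)
  fa$data[] <- ifelse(w[, 1] < 0, 0.4, 0.8)
  # one streamline of two 10 mm halves: FA 0.4 then 0.8 -> mean 0.6
  pts <- cbind(seq(-10, 10, by = 1), 0, 0)
  m <- bundle_metrics(make_bundle(list(pts)), fa)
  expect_equal(m$fiber_count, 1L)
  expect_equal(m$mean_length, 20)
  expect_equal(m$mean_fa, 0.6, tolerance = 0.03)  # one transition segment mixes
  # ten identical 30 mm streamlines through one voxel row of 1 mm^3 voxels:
  # swept volume 31 voxels, mean CS = 31/30
  pts30 <- cbind(seq(-15, 15, by = 1), 0, 0)
  ten <- bundle_metrics(make_bundle(rep(list(pts30), 10)), fa)
  expect_equal(ten$fiber_count, 10L)
  expect_equal(ten$mean_length, 30)
  expect_equal(ten$mean_cs, 31 * 1 / 30)
  # constant field: mean FA equals the constant for any bundle
  fac <- volume3d(array(0.37, d), spacing = c(1, 1, 1))
  expect_equal(bundle_metrics(make_bundle(list(pts, pts30)), fac)$mean_fa,
               0.37, tolerance = 1e-12)
  # empty bundle is flagged undefined
  e <- bundle_metrics(make_bundle(list()), fa)
  expect_false(e$defined)
  expect_equal(e$fiber_count, 0L)
  expect_true(is.na(e$mean_length))
})

test_that("ipsi/contra normalization forms ratios and flags undefined contrasts", {
  a <- structure(list(fiber_count = 50, mean_length = 20, mean_fa = 0.5,
                      mean_cs = 2, defined = TRUE), class = "bundle_metrics")
  b <- structure(list(fiber_count = 100, mean_length = 40, mean_fa = 0.6,
                      mean_cs = 4, defined = TRUE), class = "bundle_metrics")
  r <- normalize_ipsi_contra(a, b)
  expect_equal(unname(r["fiber_count"]), 0.5)
  expect_equal(unname(r["mean_length"]), 0.5)
  expect_equal(unname(r["mean_fa"]), 0.5 / 0.6)
  expect_equal(normalize_ipsi_contra(a, a), c(fiber_count = 1, mean_length = 1,
                                              mean_fa = 1, mean_cs = 1))
  e <- structure(list(fiber_count = 0L, mean_length = NA_real_,
                      mean_fa = NA_real_, mean_cs = NA_real_, defined = FALSE),
                 class = "bundle_metrics")
  expect_true(all(is.na(normalize_ipsi_contra(a, e))))
  # empty ipsilateral bundle still gives a 0 count ratio
  expect_equal(unname(normalize_ipsi_contra(e, b)["fiber_count"]), 0)
})

test_that("exact Wilcoxon signed-rank matches hand enumeration", {
  # differences {+1,+2,+3}: W = 6, p = 2/8
  r <- wilcoxon_signed_rank(c(2, 3, 4), c(1, 1, 1), mode = "exact")
  expect_equal(r$statistic, 6)
  expect_equal(r$p_value, 0.25)
  # tied magnitudes {+1,-1}: perfect symmetry, p = 1
  r2 <- wilcoxon_signed_rank(c(2, 1), c(1, 2), mode = "exact")
  expect_equal(r2$p_value, 1)
  # zero differences dropped and counted
  r3 <- wilcoxon_signed_rank(c(1, 2, 3, 5), c(1, 1, 1, 1), mode = "exact")
  expect_equal(r3$n_zero_dropped, 1L)
  expect_equal(r3$n_used, 3L)
  # all-zero differences: p undefined, flagged
  r4 <- wilcoxon_signed_rank(c(1, 2), c(1, 2))
  expect_true(is.na(r4$p_value))
  expect_error(wilcoxon_signed_rank(1:3, 1:2), "equal length")
})

test_that("exact mode agrees with brute-force enumeration for n <= 10", {
  set.seed(17)
  for (n in c(4, 6, 8, 10)) {
    for (rep in 1:5) {
      a <- round(rnorm(n), 1)
      b <- round(rnorm(n), 1)
      d <- a - b
      if (all(d == 0) || length(d[d != 0]) < 2) next
      got <- wilcoxon_signed_rank(a, b, mode = "exact")
      expect_equal(got$p_value, brute_force_wilcoxon_p(d), tolerance = 1e-12,
                   info = sprintf("n=%d rep=%d", n, rep))
    }
  }
})

test_that("exact mode agrees with stats::wilcox.test on tie-free data", {
  set.seed(18)
  a <- rnorm(12); b <- rnorm(12)
  got <- wilcoxon_signed_rank(a, b, mode = "exact")
  ref <- wilcox.test(a, b, paired = TRUE, exact = TRUE, correct = FALSE)
  expect_equal(got$statistic, unname(ref$statistic))
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-12)
})

test_that("normal approximation tracks the exact p for moderate n", {
  # with continuity correction the approximation agrees within 0.02 at
  # n = 15; the uncorrected default stays within ~0.03
  set.seed(19)
  d_cc <- c(); d_raw <- c()
  for (i in 1:20) {
    a <- rnorm(15); b <- rnorm(15)
    pe <- wilcoxon_signed_rank(a, b, mode = "exact")$p_value
    d_cc <- c(d_cc, abs(pe - wilcoxon_signed_rank(
      a, b, mode = "normal_approx", continuity = TRUE)$p_value))
    d_raw <- c(d_raw, abs(pe - wilcoxon_signed_rank(
      a, b, mode = "normal_approx")$p_value))
  }
  expect_lt(max(d_cc), 0.02)
  expect_lt(max(d_raw), 0.05)
})

test_that("asymmetry report assembles ratios, summaries, and distance tests", {
  set.seed(20)
  rows <- list()
  for (s in 1:6) for (d in c(3, 9, 15)) {
    contra <- c(100, 40, 0.7, 3)
    eff <- 1 - 0.3 * (15 - d) / 12 + rnorm(4, 0, 0.02)
    ipsi <- contra * eff
    rows[[length(rows) + 1]] <- data.frame(
      subject = s, side = c("ipsilateral", "contralateral"), distance = d,
      fiber_count = c(ipsi[1], contra[1]), mean_length = c(ipsi[2], contra[2]),
      mean_fa = c(ipsi[3], contra[3]), mean_cs = c(ipsi[4], contra[4]))
  }
  metrics <- do.call(rbind, rows)
  rep <- build_report(metrics, mode = "exact")
  expect_equal(nrow(rep$ratios), 18)
  expect_equal(nrow(rep$tests), 12)  # 3 distance pairs x 4 metrics
  # injected gradient: mean ratios increase with distance, 3 vs 15 significant
  s3 <- rep$summary[rep$summary$distance == 3 & rep$summary$metric == "mean_fa", ]
  s15 <- rep$summary[rep$summary$distance == 15 & rep$summary$metric == "mean_fa", ]
  expect_lt(s3$mean_ratio, s15$mean_ratio)
  t315 <- rep$tests[rep$tests$metric == "mean_fa" & rep$tests$distance_a == 3 &
                      rep$tests$distance_b == 15, ]
  expect_lt(t315$p_value, 0.05)
  # single distance: ratios reported, tests skipped with a notice
  one <- build_report(metrics[metrics$distance == 3, ])
  expect_null(one$tests)
  expect_match(one$notice, "single distance")
  # identical sides: all ratios 1, no significant differences
  same <- metrics
  same[, 4:7] <- matrix(rep(c(100, 40, 0.7, 3), each = nrow(same)), nrow(same))
  rep_same <- build_report(same)
  expect_true(all(abs(as.matrix(rep_same$ratios[, 3:6]) - 1) < 1e-12))
  expect_true(all(is.na(rep_same$tests$p_value)))
  # round trip through the serializer
  dir <- tempfile(); write_report(rep, dir)
  expect_true(all(file.exists(file.path(dir, c("ratios.csv", "summary.csv",
                                               "tests.json")))))
  back <- read.csv(file.path(dir, "ratios.csv"))
  expect_equal(back$mean_fa, rep$ratios$mean_fa, tolerance = 1e-12)
})
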