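test_that("overlap metrics match hand-computed cases", {
  m <- cube_mask()
  self <- overlap_metrics(m, m)
  expect_equal(self$dsc, 1)
  expect_equal(self$sen, 1)
  expect_equal(self$iou, 1)
  # |V_gt| = 8, |V_seg| = 8, intersection 4
  a <- array(0, c(4, 4, 4)); a[1:2, 1:2, 1:2] <- 1
  b <- array(0, c(4, 4, 4)); b[1:2, 1:2, 2:3] <- 1
  gt <- binary_mask(a, 0.1); seg <- binary_mask(b, 0.1)
  m2 <- overlap_metrics(gt, seg)
  expect_equal(m2$dsc, 0.5)
  expect_equal(m2$sen, 0.5)
  expect_equal(m2$iou, 1 / 3)
  expect_equal(unname(m2$counts), c(8, 8, 4, 12))
  # disjoint
  cc <- array(0, c(4, 4, 4)); cc[3:4, 3:4, 3:4] <- 1
  m3 <- overlap_metrics(gt, binary_mask(cc, 0.1))
  expect_equal(c(m3$dsc, m3$sen, m3$iou), c(0, 0, 0))
  # degenerate conventions
  e <- binary_mask(array(0, c(4, 4, 4)), 0.1)
  both <- overlap_metrics(e, e)
  expect_equal(c(both$dsc, both$sen, both$iou), c(1, 1, 1))
  ge <- overlap_metrics(e, seg)
  expect_true(ge$gt_empty)
  expect_equal(ge$sen, 0)
  # grid mismatch
  other <- binary_mask(array(0, c(4, 4, 4)), 0.2)
  expect_error(overlap_metrics(gt, other), "grids")
})

test_that("metrics agree with the exhaustive counter and satisfy identities", {
  set.seed(99)
  for (i in 1:8) {
    d <- sample(3:8, 3, replace = TRUE)
    gt <- binary_mask(array(as.numeric(runif(prod(d)) < 0.4), d), 0.1)
    seg <- binary_mask(array(as.numeric(runif(prod(d)) < 0.4), d), 0.1)
    if (mask_count(gt) == 0 || mask_count(seg) == 0) next
    got <- overlap_metrics(gt, seg)
    want <- brute_force_overlap(gt, seg)
    expect_identical(unname(got$counts), unname(want$counts))
    expect_equal(got$dsc, want$dsc)
    expect_lte(got$iou, got$dsc + 1e-12)
    expect_equal(got$dsc, 2 * got$iou / (1 + got$iou), tolerance = 1e-12)
  }
})

test_that("surface deviation is zero for identical masks and +1 voxel for a dilation", {
  m <- cube_mask(n = 10L, lo = 3L, hi = 8L)
  dev <- surface_deviation(m, m, band = 0.05)
  expect_lt(max(abs(dev$distances)), 1e-6)
  expect_equal(dev$pct_within_band, 100)
  dil <- degrade_labels(m, 1L, 0)
  dev2 <- surface_deviation(dil, m, band = 0.5)
  expect_gt(dev2$mean, 0.05)
  expect_lt(dev2$mean, 0.2)          # about one 0.1 mm voxel, corners more
  empty <- binary_mask(array(0, c(10, 10, 10)), 0.1)
  expect_error(surface_deviation(empty, m), "non-empty")
})

test_that("offset spheres give the analytic signed deviation, antisymmetrically", {
  s1 <- sphere_mask(2.0, voxel = 0.1)
  s2 <- sphere_mask(2.2, voxel = 0.1)
  # pad to the common grid
  d1 <- dim(s1$data); d2 <- dim(s2$data)
  arr <- array(0, d2)
  off <- (d2 - d1) %/% 2
  arr[off[1] + seq_len(d1[1]), off[2] + seq_len(d1[2]),
      off[3] + seq_len(d1[3])] <- s1$data
  s1p <- binary_mask(arr, 0.1)
  dev <- surface_deviation(s2, s1p, band = 0.5)
  expect_equal(dev$mean, 0.2, tolerance = 0.05)
  dev_rev <- surface_deviation(s1p, s2, band = 0.5)
  expect_equal(dev_rev$mean, -0.2, tolerance = 0.05)
})

test_that("compare_arms tabulates paired differences", {
  r1 <- list(list(dsc = 0.9, sen = 0.8, iou = 0.82),
             list(dsc = 0.7, sen = 0.6, iou = 0.55))
  same <- compare_arms(r1, r1)
  expect_equal(same$mean_diff, c(0, 0, 0))
  r2 <- lapply(r1, function(r) list(dsc = r$dsc - 0.1, sen = r$sen,
                                    iou = r$iou))
  shifted <- compare_arms(r1, r2)
  expect_equal(shifted$mean_diff[shifted$metric == "dsc"], 0.1)
  expect_error(compare_arms(r1, r1[1]), "length")
})
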