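test_that("micro-CT thresholding recovers the tooth solid and canal cavity", {
  tooth <- coarse_tooth()
  th <- threshold_uct(tooth$uct, "global", value = 550)
  expect_gte(overlap_metrics(tooth$tooth_gt, th$tooth)$dsc, 0.99)
  expect_gte(overlap_metrics(tooth$canal_gt, th$canal)$dsc, 0.95)
  flat <- volume3d(array(100, c(8, 8, 8)) +
                     array(rnorm(512), c(8, 8, 8)), 0.1)
  expect_error(threshold_uct(flat, "global", value = 1e5), "empty")
})

test_that("surface extraction finds boundary voxels and subsamples reproducibly", {
  m <- cube_mask(n = 5L, lo = 2L, hi = 4L)       # 3x3x3 solid cube
  pts <- extract_surface_points(m, max_points = 100L)
  expect_identical(nrow(pts), 26L)               # all but the centre voxel
  single <- binary_mask(array(c(rep(0, 13), 1, rep(0, 13)), c(3, 3, 3)), 0.1,
                        origin = c(1, 1, 1))
  p1 <- extract_surface_points(single, 10L)
  expect_equal(as.numeric(p1), c(1.1, 1.1, 1.1))
  big <- cube_mask(n = 12L, lo = 2L, hi = 11L)
  s1 <- extract_surface_points(big, 10L, seed = 3)
  s2 <- extract_surface_points(big, 10L, seed = 3)
  expect_identical(nrow(s1), 10L)
  expect_identical(s1, s2)
  empty <- binary_mask(array(0, c(3, 3, 3)), 0.1)
  expect_error(extract_surface_points(empty, 10L), "empty")
})

test_that("ICP self-alignment returns the identity with ~zero residual", {
  tooth <- coarse_tooth()
  th <- threshold_uct(tooth$uct, "global", value = 550)
  pts <- extract_surface_points(th$tooth, 600L, seed = 1)
  reg <- icp_register(pts, pts)
  expect_lt(max(abs(reg$transform$rotation - diag(3))), 1e-6)
  expect_lt(max(abs(reg$transform$translation)), 1e-6)
  expect_lt(reg$rms, 1e-6)
  expect_true(all(diff(reg$residuals) <= 1e-12))
})

test_that("ICP recovers a known rigid transform from phantom surfaces", {
  tooth <- coarse_tooth()
  th <- threshold_uct(tooth$uct, "global", value = 550)
  pts <- extract_surface_points(th$tooth, 600L, seed = 1)
  tr <- rigid_transform(euler_rotation(c(0, 0, 5)), c(0.3, -0.2, 0.1))
  moved <- apply_transform(tr, pts)
  reg <- icp_register(pts, moved)
  err <- compose_transforms(invert_transform(tr), reg$transform)
  expect_lt(rotation_angle_deg(err), 0.5)
  expect_lt(sqrt(sum(err$translation^2)), 0.02)
  expect_lt(reg$rms, 0.01)
})

test_that("degenerate point clouds are rejected", {
  two <- matrix(rnorm(6), 2, 3)
  good <- matrix(rnorm(30), 10, 3)
  expect_error(icp_register(two, good), "3 points")
  line <- cbind(1:10, 2 * (1:10), 3 * (1:10))
  expect_error(icp_register(line, good), "degenerate")
})

test_that("label transfer is identity on the same grid and conserves volume", {
  tooth <- coarse_tooth()
  id <- rigid_transform()
  same <- transfer_labels(tooth$tooth_gt, id, tooth$uct)
  expect_identical(same$data, tooth$tooth_gt$data)
  target <- resample_volume(tooth$uct, 0.08, "linear")
  moved <- transfer_labels(tooth$tooth_gt, id, target)
  vol_src <- mask_count(tooth$tooth_gt) * prod(tooth$tooth_gt$voxel_size)
  vol_dst <- mask_count(moved) * prod(target$voxel_size)
  expect_lt(abs(vol_dst - vol_src) / vol_src, 0.05)
})

test_that("a one-voxel-thick filament may vanish on a 0.2 mm grid", {
  arr <- array(0, c(40, 40, 40))
  arr[20, 20, 5:35] <- 1            # 30 um filament along z
  fil <- binary_mask(arr, 0.03)
  target <- volume3d(array(0, c(6, 6, 6)), 0.2)
  out <- transfer_labels(fil, rigid_transform(), target)
  expect_lte(mask_count(out), 2)
})

test_that("ground-truth fidelity is 1 at the native size and monotone for canals", {
  tooth <- coarse_tooth()
  fid <- groundtruth_fidelity(tooth$canal_gt, c(0.06, 0.1, 0.2))
  expect_equal(fid$dsc[1], 1)
  expect_true(all(diff(fid$dsc) <= 1e-9))
  cube <- cube_mask(n = 120L, lo = 5L, hi = 116L, voxel = 0.05)
  fid2 <- groundtruth_fidelity(cube, c(0.1, 0.2))
  expect_true(all(fid2$dsc >= 0.95))
})

test_that("uct_guided_labels lands transferred masks near the true pose", {
  pair <- labelled_pair()[[1]]
  true_tooth <- transfer_labels(pair$tooth_gt, pair$pose, pair$cbct)
  expect_gte(overlap_metrics(true_tooth, pair$tooth_label)$dsc, 0.9)
  expect_gt(mask_count(pair$canal_label), 0)
  expect_lt(pair$icp_rms, 0.2)
})
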