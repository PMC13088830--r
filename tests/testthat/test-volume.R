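test_that("NIfTI round-trip preserves data, voxel size and origin", {
  dir <- withr::local_tempdir()
  v <- volume3d(array(5, c(4, 4, 4)), voxel_size = 0.2,
                origin = c(1, 2, 3))
  f <- file.path(dir, "v.nii.gz")
  write_volume(v, f)
  v2 <- read_volume(f)
  expect_equal(v2$data, v$data)
  expect_equal(v2$voxel_size, v$voxel_size, tolerance = 1e-6)
  expect_equal(v2$origin, v$origin, tolerance = 1e-6)

  m <- cube_mask()
  fm <- file.path(dir, "m.nii.gz")
  write_volume(m, fm)
  m2 <- read_volume(fm)
  expect_true(all(m2$data %in% c(0, 1)))
  expect_identical(m2$data, m$data)

  set.seed(1)
  vf <- volume3d(array(rnorm(64), c(4, 4, 4)), 0.5)
  ff <- file.path(dir, "f.nii.gz")
  write_volume(vf, ff)
  expect_equal(read_volume(ff)$data, vf$data, tolerance = 1e-6)
})

test_that("phantom micro-CT written at 0.03 mm reads back at 0.03 mm", {
  dir <- withr::local_tempdir()
  small <- generate_tooth(phantom_spec(root_length = 1.2, crown_radius = 0.5,
                                       canal_radius_coronal = 0.15,
                                       canal_radius_apical = 0.08,
                                       uct_voxel = 0.03, seed = 1L))
  f <- file.path(dir, "uct.nii.gz")
  write_volume(small$uct, f)
  back <- read_volume(f)
  expect_equal(back$voxel_size, c(0.03, 0.03, 0.03), tolerance = 1e-6)
})

test_that("reading a non-3D image fails with a dimensionality message", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "flat.nii.gz")
  RNifti::writeNifti(RNifti::asNifti(matrix(1, 4, 4)), f)
  expect_error(read_volume(f), "3D")
  expect_error(read_volume(file.path(dir, "nope.nii.gz")), "no such file")
})

test_that("volume3d and binary_mask validate their invariants", {
  expect_error(volume3d(matrix(1, 2, 2), 0.1), "3D")
  expect_error(volume3d(array(NA_real_, c(2, 2, 2)), 0.1), "finite")
  expect_error(volume3d(array(1, c(2, 2, 2)), -0.1), "positive")
  expect_error(binary_mask(array(2, c(2, 2, 2)), 0.1), "0 and 1")
})

test_that("resampling a constant volume is exact in both modes", {
  v <- volume3d(array(7, c(10, 10, 6)), 0.2)
  for (mode in c("linear", "nearest")) {
    out <- resample_volume(v, 0.13, mode)
    expect_true(all(out$data == 7))
  }
})

test_that("resampling follows the world-extent shape law", {
  v <- volume3d(array(0, c(64, 64, 64)), 0.2)
  out <- resample_volume(v, 0.1)
  expect_identical(dim(out$data), c(128L, 128L, 128L))
  # world-extent conservation on random cases
  set.seed(11)
  for (i in 1:10) {
    n <- sample(5:40, 3, replace = TRUE)
    vs <- runif(1, 0.05, 0.3)
    ts <- runif(1, 0.05, 0.3)
    vv <- volume3d(array(0, n), vs)
    oo <- resample_volume(vv, ts)
    expect_true(all(abs(dim(oo$data) * ts - n * vs) <= ts + 1e-9))
  }
})

test_that("resampling at the source size with aligned origins is identity", {
  set.seed(2)
  v <- volume3d(array(rnorm(4 * 5 * 6), c(4, 5, 6)), 0.2)
  out <- resample_volume(v, 0.2, "linear")
  expect_equal(out$data, v$data, tolerance = 1e-12)
})

test_that("nearest-mode resampling keeps masks binary and linear+0.5 keeps a solid interior", {
  m <- cube_mask(n = 12L, lo = 2L, hi = 11L)
  out <- resample_volume(m, 0.07, "nearest")
  expect_s3_class(out, "binary_mask")
  expect_true(all(out$data %in% c(0, 1)))
  ones <- binary_mask(array(1, c(8, 8, 8)), 0.1)
  lin <- binarize(resample_volume(ones, 0.06, "linear"), 0.5)
  # interior of the covered region stays foreground
  expect_true(all(lin$data[2:12, 2:12, 2:12] == 1))
})

test_that("crop_to_box extracts exactly the requested half-open window", {
  arr <- array(seq_len(64), c(4, 4, 4))
  v <- volume3d(arr, 0.1, origin = c(0, 0, 0))
  full <- crop_to_box(v, crop_box(c(1, 1, 1), c(5, 5, 5)))
  expect_identical(full$data, v$data)
  sub <- crop_to_box(v, crop_box(c(1, 1, 1), c(3, 3, 3)))
  expect_identical(sub$data, arr[1:2, 1:2, 1:2])
  shifted <- crop_to_box(v, crop_box(c(2, 3, 4), c(4, 5, 5)))
  expect_equal(shifted$origin, c(0.1, 0.2, 0.3))
  expect_error(crop_box(c(1, 1, 1), c(1, 5, 5)), "hi > lo")
  expect_error(crop_to_box(v, crop_box(c(1, 1, 1), c(6, 5, 5))), "exceeds")
  # cropping is idempotent for the full box of the crop
  again <- crop_to_box(sub, crop_box(c(1, 1, 1), c(3, 3, 3)))
  expect_identical(again$data, sub$data)
})

test_that("tooth_crop_box centres the window and pads z by the margin", {
  arr <- array(0, c(32, 32, 20))
  arr[16, 16, 10] <- 1
  m <- binary_mask(arr, 0.1)
  box <- tooth_crop_box(m, axial_size = 16L, z_margin = 4L)
  expect_identical(box$hi[1:2] - box$lo[1:2], c(16L, 16L))
  expect_identical(box$hi[3] - box$lo[3], 9L)     # 1 + 2 * 4
  expect_true(box$lo[1] <= 16 && box$hi[1] > 16)
  # mask touching z = 1 clamps
  arr2 <- array(0, c(16, 16, 8)); arr2[8, 8, 1] <- 1
  box2 <- tooth_crop_box(binary_mask(arr2, 0.1), 8L, z_margin = 4L)
  expect_identical(box2$lo[3], 1L)
  expect_error(tooth_crop_box(binary_mask(array(0, c(4, 4, 4)), 0.1), 4L),
               "empty")
  arr3 <- array(1, c(16, 16, 4))
  expect_error(tooth_crop_box(binary_mask(arr3, 0.1), 8L), "smaller")
})

test_that("binarize sends threshold ties to foreground and counts agree", {
  v <- volume3d(array(0.6, c(3, 3, 3)), 0.1)
  expect_equal(mask_count(binarize(v, 0.5)), 27)
  v2 <- volume3d(array(0.5, c(2, 2, 2)), 0.1)
  expect_equal(mask_count(binarize(v2, 0.5)), 8)
  set.seed(3)
  v3 <- volume3d(array(runif(125), c(5, 5, 5)), 0.1)
  m <- binarize(v3, 0.4)
  expect_equal(mask_count(m), sum(v3$data >= 0.4))
})
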