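test_that("connected components respect the adjacency definition", {
  e <- binary_mask(array(0, c(4, 4, 4)), 0.1)
  expect_identical(connected_components(e)$n, 0L)
  # two voxels touching only at a corner
  arr <- array(0, c(4, 4, 4))
  arr[2, 2, 2] <- 1; arr[3, 3, 3] <- 1
  m <- binary_mask(arr, 0.1)
  expect_identical(connected_components(m, 6L)$n, 2L)
  expect_identical(connected_components(m, 26L)$n, 1L)
  cube <- cube_mask(n = 6L, lo = 2L, hi = 5L)
  cs <- connected_components(cube)
  expect_identical(cs$n, 1L)
  expect_identical(cs$components$size, 64L)
})

test_that("false-positive removal policies keep the right components", {
  arr <- array(0, c(12, 12, 12))
  arr[2:6, 2:6, 2:5] <- 1            # 100 voxels
  arr[9:10, 9:10, 9] <- 1            # 4 voxels (+1 below = 5)
  arr[9, 9, 10] <- 1
  m <- binary_mask(arr, 0.1)
  keep1 <- remove_false_positives(m, "keep_largest_k", k = 1L)
  expect_equal(mask_count(keep1), 100)
  expect_identical(connected_components(keep1)$n, 1L)
  expect_identical(remove_false_positives(m, "min_size", min_voxels = 1L)$data,
                   m$data)
  small_gone <- remove_false_positives(m, "min_size", min_voxels = 10L)
  expect_equal(mask_count(small_gone), 100)
  expect_error(remove_false_positives(m, "keep_largest_k", k = 0L), "k")
  expect_error(remove_false_positives(m, "keep_in_region",
                                      region = binary_mask(array(0, c(12, 12, 12)), 0.1)),
               "empty region")
})

test_that("keep_in_region removes a coronal blob but keeps the canal", {
  # tooth: wide at z 16-24 (crown), narrow below; canal tube in the root,
  # false-positive blob in the crown
  arr_tooth <- array(0, c(24, 24, 26))
  arr_tooth[9:16, 9:16, 2:15] <- 1
  arr_tooth[5:20, 5:20, 16:24] <- 1
  tooth <- binary_mask(arr_tooth, 0.1)
  pred <- array(0, c(24, 24, 26))
  pred[12:13, 12:13, 3:14] <- 1          # canal
  canal_count <- sum(pred)
  pred[7:9, 7:9, 19:21] <- 1             # coronal blob
  pred_m <- binary_mask(pred, 0.1)
  region <- radicular_region(tooth)
  cleaned <- remove_false_positives(pred_m, "keep_in_region",
                                    region = region)
  expect_equal(mask_count(cleaned), canal_count)
  # DSC vs the canal-only ground truth improves
  gt <- binary_mask(array(as.numeric(pred * 0), dim(pred)), 0.1)
  gt$data[12:13, 12:13, 3:14] <- 1
  expect_gte(overlap_metrics(gt, cleaned)$dsc,
             overlap_metrics(gt, pred_m)$dsc)
})

test_that("removal output is a subset of its input and idempotent", {
  set.seed(4)
  arr <- array(as.numeric(runif(16^3) < 0.2), c(16, 16, 16))
  m <- binary_mask(arr, 0.1)
  for (pol in list(list(policy = "keep_largest_k", k = 2L),
                   list(policy = "min_size", min_voxels = 5L))) {
    once <- do.call(remove_false_positives, c(list(m), pol))
    expect_true(all(once$data <= m$data))
    twice <- do.call(remove_false_positives, c(list(once), pol))
    expect_identical(twice$data, once$data)
  }
})
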