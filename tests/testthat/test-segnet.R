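test_that("the tiny variant stays under a million parameters and is seeded", {
  cfg <- net_config("tiny")
  m1 <- build_model(cfg, seed = 3)
  expect_lt(model_parameter_count(m1), 1e6)
  m2 <- build_model(cfg, seed = 3)
  expect_identical(m1$params, m2$params)
  m3 <- build_model(cfg, seed = 4)
  expect_false(identical(m1$params$enc[[1]]$conv_in$W,
                         m3$params$enc[[1]]$conv_in$W))
  expect_error(net_config("custom"), "custom")
  expect_error(net_config("custom",
                          stages = list(list(depth = 2, mid = 4, out = 8)),
                          bottom = list(depth = 2, mid = 4, out = 8)),
               "stages")
})

test_that("forward pass returns a finite probability map of the input shape", {
  cfg <- mini_net_config()
  model <- build_model(cfg, seed = 1)
  vol <- volume3d(array(0, c(24, 24, 3)), 0.1)
  prob <- predict_volume(model, vol)
  expect_identical(dim(prob$data), c(24L, 24L, 3L))
  expect_true(all(is.finite(prob$data)))
  expect_true(all(prob$data >= 0 & prob$data <= 1))
  # non-multiple-of-factor extents are padded internally and cropped back
  odd <- volume3d(array(rnorm(21 * 18 * 2), c(21, 18, 2)), 0.1)
  prob2 <- predict_volume(model, odd)
  expect_identical(dim(prob2$data), c(21L, 18L, 2L))
  expect_true(all(prob2$data >= 0 & prob2$data <= 1))
})

test_that("constant input slices give spatially constant output", {
  cfg <- mini_net_config()
  model <- build_model(cfg, seed = 2)
  vol <- volume3d(array(rep(c(0, 1), each = 16 * 16), c(16, 16, 2)), 0.1)
  prob <- predict_volume(model, vol)
  for (k in 1:2) {
    sl <- prob$data[, , k]
    # near-constant away from the zero-padded border (padding breaks exact
    # translation invariance within the network's receptive field)
    expect_lt(diff(range(sl[6:11, 6:11])), 1e-3)
  }
})

test_that("all deep-supervision outputs are valid probabilities", {
  cfg <- mini_net_config()
  model <- build_model(cfg, seed = 5)
  set.seed(1)
  x <- array(runif(16 * 16), c(16, 16, 1))
  fw <- canalseg:::net_fwd(model$params, cfg, x)
  for (l in c(list(fw$fused), fw$sides)) {
    p <- canalseg:::sigmoid(l)
    expect_identical(dim(p)[1:2], c(16L, 16L))
    expect_true(all(p >= 0 & p <= 1))
  }
})

test_that("checkpoints round-trip the model bit for bit", {
  dir <- withr::local_tempdir()
  cfg <- mini_net_config()
  model <- build_model(cfg, seed = 6)
  path <- file.path(dir, "model.ckpt")
  save_checkpoint(model, path)
  expect_true(file.exists(paste0(path, ".json")))
  back <- load_checkpoint(path)
  expect_identical(back$params, model$params)
  vol <- volume3d(array(rnorm(16 * 16 * 2), c(16, 16, 2)), 0.1)
  expect_identical(predict_volume(back, vol)$data,
                   predict_volume(model, vol)$data)
})
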