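test_that("rigid transforms validate, compose and invert correctly", {
  expect_error(rigid_transform(matrix(1, 3, 3)), "orthonormal")
  refl <- diag(c(-1, 1, 1))
  expect_error(rigid_transform(refl), "determinant")
  a <- rigid_transform(euler_rotation(c(10, -5, 20)), c(1, 2, 3))
  b <- rigid_transform(euler_rotation(c(-3, 8, 0)), c(-1, 0.5, 0))
  pts <- matrix(rnorm(15), 5, 3)
  expect_equal(apply_transform(compose_transforms(a, b), pts),
               apply_transform(a, apply_transform(b, pts)))
  ia <- invert_transform(a)
  expect_equal(apply_transform(ia, apply_transform(a, pts)), pts)
  expect_equal(rotation_angle_deg(rigid_transform()), 0)
  rz <- rigid_transform(euler_rotation(c(0, 0, 30)))
  expect_equal(rotation_angle_deg(rz), 30, tolerance = 1e-9)
})
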