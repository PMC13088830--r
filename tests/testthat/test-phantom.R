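test_that("generated teeth satisfy containment, intensity ordering and determinism", {
  tooth <- coarse_tooth()
  expect_true(all(tooth$canal_gt$data <= tooth$tooth_gt$data))
  ints <- list(enamel = 2000, dentin = 1000, canal = 100)
  canal <- tooth$canal_gt$data == 1
  dentin_region <- tooth$tooth_gt$data == 1 & !canal
  bg <- tooth$tooth_gt$data == 0
  expect_gt(mean(tooth$uct$data[dentin_region]), mean(tooth$uct$data[canal]))
  expect_gt(max(tooth$uct$data[dentin_region]), ints$dentin)  # enamel shell
  # seeded determinism
  spec <- phantom_spec(root_length = 3.5, crown_radius = 1.3,
                       uct_voxel = 0.06, seed = 42L)
  again <- generate_tooth(spec)
  expect_identical(again$uct$data, tooth$uct$data)
  expect_identical(again$canal_gt$data, tooth$canal_gt$data)
})

test_that("intensity ordering holds across seeds and anatomy classes", {
  for (seed in c(1L, 2L)) {
    sp <- phantom_spec("M", n_roots = 2L, root_length = 3, crown_radius = 1.3,
                       isthmus = TRUE, uct_voxel = 0.08, seed = seed)
    tt <- generate_tooth(sp)
    enamel_like <- tt$uct$data > 1500
    expect_gt(sum(enamel_like), 0)
    canal <- tt$canal_gt$data == 1
    dentin <- tt$tooth_gt$data == 1 & !canal & !enamel_like
    expect_gt(mean(tt$uct$data[enamel_like]), mean(tt$uct$data[dentin]))
    expect_gt(mean(tt$uct$data[dentin]), mean(tt$uct$data[canal]))
    expect_true(all(tt$canal_gt$data <= tt$tooth_gt$data))
  }
})

test_that("a plain single-rooted canal is one 26-connected component", {
  sp <- phantom_spec(root_length = 3.5, crown_radius = 1.3,
                     canal_curvature = 0, accessory_canal = FALSE,
                     uct_voxel = 0.05, seed = 7L)
  tt <- generate_tooth(sp)
  cc <- connected_components(tt$canal_gt, 26L)
  expect_identical(cc$n, 1L)
})

test_that("phantom_spec validates anatomy constraints", {
  expect_error(phantom_spec("SR", n_roots = 2L), "single-rooted")
  expect_error(phantom_spec(canal_radius_coronal = 0.1,
                            canal_radius_apical = 0.2), "apical")
  expect_error(phantom_spec(intensities = list(enamel = 10, dentin = 20,
                                               canal = 5)), "intensities")
  expect_error(phantom_spec("SR", isthmus = TRUE), "two canals|molar")
})

test_that("simulate_cbct degenerates to a pure resample and is seeded", {
  # thick-walled tooth so the mid-root dentin has a > 3 sigma margin from
  # both the canal and the outer surface
  thick <- generate_tooth(phantom_spec(root_length = 5, crown_radius = 2.2,
                                       canal_radius_coronal = 0.3,
                                       canal_radius_apical = 0.12,
                                       uct_voxel = 0.06, seed = 8L))
  cbb <- simulate_cbct(thick$uct, 0.1, psf_sigma = 0.1, noise_sd = 0)
  # blur conserves the local mean away from edges: compare root dentin
  # (tooth minus safety margins, mid-root slab, below the enamel) against
  # the nominal dentin mean
  tooth_m <- transfer_labels(thick$tooth_gt, rigid_transform(), cbb)
  canal_m <- transfer_labels(thick$canal_gt, rigid_transform(), cbb)
  d <- dim(tooth_m$data)
  interior <- canalseg:::cpp_dilate(as.integer(tooth_m$data == 0), d,
                                    3L, 26L) == 0L
  near_canal <- canalseg:::cpp_dilate(as.integer(canal_m$data), d,
                                      3L, 26L) == 1L
  slab <- array(FALSE, d)
  zmid <- round(d[3] * c(0.25, 0.5))
  slab[, , zmid[1]:zmid[2]] <- TRUE
  core_idx <- which(interior & !near_canal & slab)
  expect_gt(length(core_idx), 50)
  expect_lt(abs(mean(cbb$data[core_idx]) - 1000) / 1000, 0.01)
  tooth <- coarse_tooth()
  # seeded reproducibility; different seeds differ only in noise
  p <- rigid_transform(euler_rotation(c(2, 1, -3)), c(0.3, 0.1, -0.2))
  c1 <- simulate_cbct(tooth$uct, 0.2, 0.2, noise_sd = 40, pose = p, seed = 3)
  c2 <- simulate_cbct(tooth$uct, 0.2, 0.2, noise_sd = 40, pose = p, seed = 3)
  c3 <- simulate_cbct(tooth$uct, 0.2, 0.2, noise_sd = 40, pose = p, seed = 4)
  expect_identical(c1$data, c2$data)
  base <- simulate_cbct(tooth$uct, 0.2, 0.2, noise_sd = 0, pose = p)
  d13 <- c1$data - base$data
  d34 <- c3$data - base$data
  expect_false(identical(d13, d34))
  expect_equal(dim(c1$data), dim(c3$data))
  expect_error(simulate_cbct(tooth$uct, 0.01), "larger")
})

test_that("contrast between canal and dentin drops at coarser CBCT voxels", {
  tooth <- coarse_tooth()
  sep <- function(voxel) {
    cb <- simulate_cbct(tooth$uct, voxel, psf_sigma = voxel, noise_sd = 50,
                        seed = 1)
    canal <- transfer_labels(tooth$canal_gt, rigid_transform(), cb)
    tooth_m <- transfer_labels(tooth$tooth_gt, rigid_transform(), cb)
    a <- cb$data[canal$data == 1]
    b <- cb$data[tooth_m$data == 1 & canal$data == 0]
    (mean(b) - mean(a)) / sqrt((var(a) + var(b)) / 2)
  }
  expect_lt(sep(0.2), sep(0.08))
})

test_that("degrade_labels dilates, keeps full recall, and is monotone", {
  m <- cube_mask(n = 9L, lo = 4L, hi = 6L)
  expect_identical(degrade_labels(m, 0L, 0)$data, m$data)
  d1 <- degrade_labels(m, 1L, 0)
  oracle <- brute_force_dilate(m$data)
  expect_equal(d1$data, oracle)
  met <- overlap_metrics(m, d1)
  expect_equal(met$sen, 1)
  prec <- met$counts["n_intersection"] / met$counts["n_seg"]
  expect_lt(prec, 1)
  counts <- vapply(0:3, function(k)
    mask_count(degrade_labels(m, k, 0)), numeric(1))
  expect_true(all(diff(counts) >= 0))
  # jittered degradation keeps the eroded core and is seeded
  j1 <- degrade_labels(m, 1L, boundary_jitter_sd = 1, seed = 2)
  j2 <- degrade_labels(m, 1L, boundary_jitter_sd = 1, seed = 2)
  expect_identical(j1$data, j2$data)
  expect_true(all(j1$data[5, 5, 5] == 1))
})

test_that("generate_cohort is reproducible and satisfies pair invariants", {
  expect_identical(generate_cohort(0, 0), list())
  c1 <- generate_cohort(2, 1, voxel = 0.2, seed = 9L, uct_voxel = 0.08)
  c2 <- generate_cohort(2, 1, voxel = 0.2, seed = 9L, uct_voxel = 0.08)
  expect_identical(c1[[1]]$uct$data, c2[[1]]$uct$data)
  expect_identical(c1[[3]]$cbct$data, c2[[3]]$cbct$data)
  for (pair in c1) {
    expect_true(all(pair$canal_gt$data <= pair$tooth_gt$data))
    expect_identical(dim(pair$canal_gt$data), dim(pair$uct$data))
    expect_false(identical(dim(pair$cbct$data), dim(pair$uct$data)))
    expect_lte(rotation_angle_deg(pair$pose), 10)
    expect_lte(max(abs(pair$pose$translation)), 1)
    expect_gt(mask_count(pair$canal_gt), 0)
  }
  expect_identical(c1[[1]]$spec$tooth_class, "SR")
  expect_identical(c1[[3]]$spec$tooth_class, "M")
})
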