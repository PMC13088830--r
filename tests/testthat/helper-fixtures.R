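# Shared fixtures, built once per test run. Coarse voxel sizes keep the
# module tests fast; the acceptance tests build their own full-resolution
# phantoms.

fixture_env <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = fixture_env))
    assign(key, builder(), envir = fixture_env)
  get(key, envir = fixture_env)
}

# small single-rooted tooth rendered coarsely (fast)
coarse_tooth <- function() memo("coarse_tooth", function() {
  generate_tooth(phantom_spec(root_length = 3.5, crown_radius = 1.3,
                              uct_voxel = 0.06, seed = 42L))
})

# a labelled one-tooth cohort at 80 um CBCT (coarse micro-CT for speed)
labelled_pair <- function() memo("labelled_pair", function() {
  cohort <- generate_cohort(1, 0, voxel = 0.08, seed = 5L,
                            uct_voxel = 0.05)
  transfer_cohort_labels(cohort)
})

# solid cube mask in an empty volume
cube_mask <- function(n = 8L, lo = 3L, hi = 6L, voxel = 0.1) {
  arr <- array(0, c(n, n, n))
  arr[lo:hi, lo:hi, lo:hi] <- 1
  binary_mask(arr, voxel)
}

# digital sphere mask of radius r (mm) on a grid with given voxel (mm)
sphere_mask <- function(r, voxel = 0.1, pad = 4L) {
  n <- 2L * (ceiling(r / voxel) + pad) + 1L
  c0 <- (n + 1) / 2
  idx <- (seq_len(n) - c0) * voxel
  d2 <- outer(outer(idx^2, idx^2, "+"), idx^2, "+")
  binary_mask(array(as.numeric(d2 <= r^2), c(n, n, n)), voxel)
}

# independent triple-loop voxel-overlap counter (oracle for the metrics)
brute_force_overlap <- function(gt, seg) {
  d <- dim(gt$data)
  n_gt <- 0L; n_seg <- 0L; n_int <- 0L
  for (k in seq_len(d[3]))
    for (j in seq_len(d[2]))
      for (i in seq_len(d[1])) {
        g <- gt$data[i, j, k]; s <- seg$data[i, j, k]
        n_gt <- n_gt + (g == 1)
        n_seg <- n_seg + (s == 1)
        n_int <- n_int + (g == 1 && s == 1)
      }
  n_uni <- n_gt + n_seg - n_int
  list(dsc = 2 * n_int / (n_gt + n_seg), sen = n_int / n_gt,
       iou = n_int / n_uni,
       counts = c(n_gt = n_gt, n_seg = n_seg, n_intersection = n_int,
                  n_union = n_uni))
}

# independent 26-neighbourhood dilation oracle
brute_force_dilate <- function(arr) {
  d <- dim(arr)
  out <- array(0, d)
  for (k in seq_len(d[3]))
    for (j in seq_len(d[2]))
      for (i in seq_len(d[1])) {
        if (arr[i, j, k] != 1) next
        for (dk in -1:1) for (dj in -1:1) for (di in -1:1) {
          ii <- i + di; jj <- j + dj; kk <- k + dk
          if (ii >= 1 && jj >= 1 && kk >= 1 &&
              ii <= d[1] && jj <= d[2] && kk <= d[3])
            out[ii, jj, kk] <- 1
        }
      }
  out
}

# tiny network for fast wiring tests (pad multiple 8)
mini_net_config <- function() {
  net_config("custom",
             stages = list(list(depth = 2L, mid = 4L, out = 8L),
                           list(depth = 2L, mid = 4L, out = 8L)),
             bottom = list(depth = 2L, mid = 4L, out = 8L))
}

# toy training pair: bright square on dark background, constant across z
toy_pair <- function(n = 16L, nz = 6L, voxel = 0.1) {
  img <- array(0, c(n, n, nz))
  lab <- array(0, c(n, n, nz))
  img[5:12, 5:12, ] <- 1
  lab[5:12, 5:12, ] <- 1
  img <- img + array(rnorm(n * n * nz, sd = 0.05), c(n, n, nz))
  list(image = volume3d(img, voxel), label = binary_mask(lab, voxel),
       tooth_mask = NULL, tooth_id = 1L, group = "SR", voxel = voxel)
}
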