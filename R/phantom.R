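#' Parametric description of a synthetic tooth
#'
#' A `phantom_spec` describes a desk-scale tooth phantom: a crown (enamel
#' shell over a dentin core) on 1-3 tapered roots, each carrying a tapering
#' canal that opens into a pulp chamber. Optional features cover the canal
#' anatomy classes seen in extracted-tooth studies: a quadratic apical bend
#' (curved canals), an accessory canal branching off the main canal, an
#' isthmus sheet connecting two canals (molars), and a C-shaped arc
#' cross-section sweep (molars).
#'
#' The canal ends slightly short of the anatomical apex
#' (`apex_clearance`) and accessory canals stop just short of the root
#' surface, so the whole canal system is an interior cavity of the tooth
#' solid; this mirrors the apical constriction and keeps the cavity
#' recoverable from a single threshold of the micro-CT rendering.
#'
#' @param tooth_class `"SR"` (single-rooted) or `"M"` (molar).
#' @param n_roots number of roots (1 for SR, 1-3 for M).
#' @param root_length root length in mm (apex at z = 0).
#' @param crown_radius crown radius in mm.
#' @param canal_radius_coronal,canal_radius_apical canal tube radius (mm) at
#'   the chamber end and the apical end; apical must not exceed coronal.
#' @param canal_curvature apical bend magnitude in mm (0 = straight).
#' @param accessory_canal logical; add a lateral accessory canal.
#' @param accessory_level branch height as a fraction of root length.
#' @param isthmus logical (M only); add an isthmus sheet between canals.
#' @param c_shaped logical (M only); sweep the canal as a C-shaped arc.
#' @param intensities named list with `enamel`, `dentin`, `canal` mean
#'   intensities; must satisfy enamel > dentin > canal.
#' @param uct_voxel micro-CT voxel size in mm.
#' @param seed integer seed controlling the rendering noise.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(tooth_class = c("SR", "M"),
                         n_roots = 1L,
                         root_length = 5,
                         crown_radius = 1.6,
                         canal_radius_coronal = 0.35,
                         canal_radius_apical = 0.15,
                         canal_curvature = 0,
                         accessory_canal = FALSE,
                         accessory_level = 0.3,
                         isthmus = FALSE,
                         c_shaped = FALSE,
                         intensities = list(enamel = 2000, dentin = 1000,
                                            canal = 100),
                         uct_voxel = 0.03,
                         seed = 1L) {
  tooth_class <- match.arg(tooth_class)
  n_roots <- as.integer(n_roots)
  if (tooth_class == "SR" && n_roots != 1L)
    stop("single-rooted (SR) phantoms must have n_roots = 1")
  if (n_roots < 1L || n_roots > 3L) stop("n_roots must be 1, 2 or 3")
  if (canal_radius_apical <= 0 || canal_radius_coronal <= 0)
    stop("canal radii must be positive")
  if (canal_radius_apical > canal_radius_coronal)
    stop("canal_radius_apical must not exceed canal_radius_coronal")
  if (!(intensities$enamel > intensities$dentin &&
        intensities$dentin > intensities$canal))
    stop("intensities must satisfy enamel > dentin > canal")
  if (isthmus && n_roots < 2L)
    stop("an isthmus requires at least two canals (n_roots >= 2)")
  if ((isthmus || c_shaped) && tooth_class != "M")
    stop("isthmus and C-shaped canals are molar (M) features")
  structure(list(tooth_class = tooth_class, n_roots = n_roots,
                 root_length = root_length, crown_radius = crown_radius,
                 canal_radius_coronal = canal_radius_coronal,
                 canal_radius_apical = canal_radius_apical,
                 canal_curvature = canal_curvature,
                 accessory_canal = isTRUE(accessory_canal),
                 accessory_level = accessory_level,
                 isthmus = isTRUE(isthmus), c_shaped = isTRUE(c_shaped),
                 intensities = intensities, uct_voxel = uct_voxel,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# root axis positions at apex and crown junction, per root, in mm.
# C-shaped teeth use a single fused trunk (as in C-shaped molars).
root_layout <- function(spec) {
  r <- spec$crown_radius
  if (spec$c_shaped) {
    apex <- matrix(c(0, 0), 1)
    cor  <- matrix(c(0, 0), 1)
    return(list(apex = apex, coronal = cor, r_apex = 0.55 * r,
                r_coronal = 0.82 * r))
  }
  if (spec$n_roots == 1L) {
    apex <- matrix(c(0, 0), 1)
    cor  <- matrix(c(0, 0), 1)
  } else if (spec$n_roots == 2L) {
    apex <- rbind(c(-0.5 * r, 0), c(0.5 * r, 0))
    cor  <- rbind(c(-0.32 * r, 0), c(0.32 * r, 0))
  } else {
    ang <- c(90, 210, 330) * pi / 180
    apex <- cbind(0.5 * r * cos(ang), 0.5 * r * sin(ang))
    cor  <- cbind(0.32 * r * cos(ang), 0.32 * r * sin(ang))
  }
  root_r_cor <- if (spec$n_roots == 1L) 0.85 * r else 0.48 * r
  list(apex = apex, coronal = cor, r_apex = 0.3, r_coronal = root_r_cor)
}

#' Render a synthetic tooth at micro-CT resolution
#'
#' Voxelizes the tooth described by a [phantom_spec()] on an isotropic grid
#' (default 30 um) and renders a micro-CT-like intensity volume: per-tissue
#' mean intensities plus Gaussian noise with sd equal to 2% of the dentin
#' mean. The apex sits near z = 0 and the crown at the top of the grid.
#'
#' @param spec a [phantom_spec()].
#' @return A list with elements `uct` ([volume3d()]), `tooth_gt` and
#'   `canal_gt` ([binary_mask()]s on the same grid; `canal_gt` is contained
#'   in `tooth_gt`). Deterministic for a fixed `spec$seed`.
#' @export
generate_tooth <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  vx <- spec$uct_voxel
  ch <- 1.2 * spec$crown_radius              # crown height
  margin <- 0.3
  half_xy <- spec$crown_radius + spec$canal_curvature + margin
  zmax <- spec$root_length + ch + margin
  x <- seq(-half_xy, half_xy, by = vx)
  y <- x
  z <- seq(-margin, zmax, by = vx)
  nx <- length(x); ny <- length(y); nz <- length(z)
  lay <- root_layout(spec)
  n_trunks <- nrow(lay$apex)
  apex_clear <- 0.3
  r_acc <- 0.4 * spec$canal_radius_apical
  rl <- spec$root_length
  zc <- rl + ch / 2                          # crown ellipsoid centre
  crown_ry <- 0.85                           # in-plane ellipticity (y/x)
  z_cervix <- rl + 0.35 * ch                 # roots merge into the crown here
  z_conv <- rl + 0.3 * ch                    # canals converge into the chamber
  chamber_c <- rl + 0.3 * ch
  chamber_rx <- 0.45 * spec$crown_radius
  chamber_rz <- 0.3 * ch

  tooth <- array(FALSE, c(nx, ny, nz))
  canal <- array(FALSE, c(nx, ny, nz))
  enamel <- array(FALSE, c(nx, ny, nz))
  X <- matrix(x, nx, ny)
  Y <- matrix(y, nx, ny, byrow = TRUE)

  for (k in seq_len(nz)) {
    zz <- z[k]
    sl_tooth <- matrix(FALSE, nx, ny)
    sl_canal <- matrix(FALSE, nx, ny)
    uu <- min(max(zz / rl, 0), 1)
    bend <- spec$canal_curvature * (1 - uu)^2
    axes <- NULL
    if (zz >= 0 && zz <= z_cervix) {
      # tapered root trunks; above the anatomical root length they continue
      # at their coronal section until merged into the crown
      for (r in seq_len(n_trunks)) {
        ax <- lay$apex[r, 1] + (lay$coronal[r, 1] - lay$apex[r, 1]) * uu + bend
        ay <- lay$apex[r, 2] + (lay$coronal[r, 2] - lay$apex[r, 2]) * uu
        rr <- lay$r_apex + (lay$r_coronal - lay$r_apex) * uu
        sl_tooth <- sl_tooth | ((X - ax)^2 + (Y - ay)^2 <= rr^2)
        axes <- rbind(axes, c(ax, ay))
      }
      # dentin web bridging the roots where an isthmus runs
      if (spec$isthmus && !spec$c_shaped && n_trunks >= 2L &&
          uu >= 0.3 && uu <= 0.7) {
        p1 <- axes[1, ]; p2 <- axes[2, ]
        v <- p2 - p1; L2 <- sum(v^2)
        tproj <- pmin(1, pmax(0, ((X - p1[1]) * v[1] + (Y - p1[2]) * v[2]) / L2))
        d2 <- (X - (p1[1] + tproj * v[1]))^2 + (Y - (p1[2] + tproj * v[2]))^2
        sl_tooth <- sl_tooth | (d2 <= 0.3^2)
      }
      # canal lumens (capped short of the apex)
      if (zz >= apex_clear) {
        rc <- spec$canal_radius_apical +
          (spec$canal_radius_coronal - spec$canal_radius_apical) * uu
        if (spec$c_shaped) {
          arc_r <- 0.45 * spec$crown_radius * (0.4 + 0.6 * uu)
          dx <- X - bend; dy <- Y
          rho <- sqrt(dx^2 + dy^2)
          theta <- atan2(dy, dx)
          sl_canal <- sl_canal |
            (abs(rho - arc_r) <= rc & abs(theta) <= 2 * pi / 3)
        } else {
          # above the root length, lumens converge towards the chamber axis
          vv <- if (zz <= rl) 0 else min((zz - rl) / (z_conv - rl), 1)
          for (r in seq_len(n_trunks)) {
            cx <- axes[r, 1] * (1 - vv)
            cy <- axes[r, 2] * (1 - vv)
            sl_canal <- sl_canal | ((X - cx)^2 + (Y - cy)^2 <= rc^2)
          }
        }
        if (spec$isthmus && !spec$c_shaped && n_trunks >= 2L &&
            uu >= 0.4 && uu <= 0.6) {
          # thin isthmus sheet between canals 1 and 2
          p1 <- axes[1, ]; p2 <- axes[2, ]
          v <- p2 - p1; L2 <- sum(v^2)
          tproj <- pmin(1, pmax(0, ((X - p1[1]) * v[1] + (Y - p1[2]) * v[2]) / L2))
          d2 <- (X - (p1[1] + tproj * v[1]))^2 + (Y - (p1[2] + tproj * v[2]))^2
          sl_canal <- sl_canal | (d2 <= 0.08^2)
        }
      }
    }
    # crown: elliptical cross-section, enamel shell over dentin core
    ez <- (zz - zc) / (ch / 2)
    if (abs(ez) <= 1) {
      s2 <- 1 - ez^2
      crown <- ((X / spec$crown_radius)^2 +
                  (Y / (crown_ry * spec$crown_radius))^2 <= s2)
      sl_tooth <- sl_tooth | crown
      ez_in <- (zz - zc) / (0.78 * ch / 2)
      inner <- if (abs(ez_in) <= 1)
        ((X / (0.78 * spec$crown_radius))^2 +
           (Y / (0.78 * crown_ry * spec$crown_radius))^2 <= 1 - ez_in^2)
      else matrix(FALSE, nx, ny)
      enamel[, , k] <- crown & !inner
    }
    # pulp chamber cavity
    cz <- (zz - chamber_c) / chamber_rz
    if (abs(cz) <= 1) {
      sl_canal <- sl_canal |
        ((X / chamber_rx)^2 + (Y / (crown_ry * chamber_rx))^2 <= 1 - cz^2)
    }
    # accessory canal: lateral tube at the branch level, stopping short of
    # the root surface
    if (spec$accessory_canal) {
      zb <- spec$accessory_level * rl
      if (abs(zz - zb) <= r_acc + vx) {
        ub <- zb / rl
        axb <- lay$apex[1, 1] +
          (lay$coronal[1, 1] - lay$apex[1, 1]) * ub +
          spec$canal_curvature * (1 - ub)^2
        ayb <- lay$apex[1, 2] + (lay$coronal[1, 2] - lay$apex[1, 2]) * ub
        rrb <- lay$r_apex + (lay$r_coronal - lay$r_apex) * ub
        ylen <- max(rrb - 0.15, 0.1)
        sl_canal <- sl_canal |
          (sqrt((X - axb)^2 + (zz - zb)^2) <= r_acc &
             Y >= ayb & Y <= ayb + ylen)
      }
    }
    tooth[, , k] <- sl_tooth
    canal[, , k] <- sl_canal
  }
  canal <- canal & tooth
  enamel <- enamel & tooth & !canal

  ints <- spec$intensities
  img <- array(ints$canal, c(nx, ny, nz))
  img[tooth] <- ints$dentin
  img[enamel] <- ints$enamel
  img[canal] <- ints$canal
  set.seed(spec$seed)
  img <- img + rnorm(length(img), sd = 0.02 * ints$dentin)
  origin <- c(x[1], y[1], z[1])
  list(uct = volume3d(img, vx, origin),
       tooth_gt = binary_mask(array(as.numeric(tooth), dim(tooth)), vx, origin),
       canal_gt = binary_mask(array(as.numeric(canal), dim(canal)), vx, origin))
}

# Resample `src` onto an explicit output grid, pulling world coordinates
# back through the inverse of `transform` (moving -> fixed convention).
pullback_resample <- function(src, transform, out_dim, out_voxel, out_origin,
                              mode = c("linear", "nearest"), fill = NULL) {
  mode <- match.arg(mode)
  if (is.null(fill)) fill <- min(src$data)
  Rinv <- t(transform$rotation)
  Dinv <- diag(1 / src$voxel_size)
  A <- Dinv %*% Rinv %*% diag(rep_len(out_voxel, 3L))
  b <- as.numeric(Dinv %*% (Rinv %*% (out_origin - transform$translation) -
                              src$origin))
  arr <- cpp_affine_resample(src$data, as.integer(out_dim), A, b,
                             mode == "linear", fill)
  volume3d(arr, out_voxel, out_origin)
}

#' Simulate a CBCT rendering of a micro-CT volume
#'
#' Degrades a high-resolution volume into a CBCT-like one: apply a rigid
#' pose offset, convolve with an isotropic Gaussian point-spread function,
#' resample linearly to the (coarser) target voxel size, and add Gaussian
#' noise. Each step is optional via zero parameters; the result is
#' deterministic per seed.
#'
#' @param uct a [volume3d()] (typically the micro-CT rendering).
#' @param target_voxel target voxel size in mm (0.2 or 0.08 in the study
#'   protocols); must exceed the source voxel size.
#' @param psf_sigma Gaussian PSF width in mm (default: one target voxel).
#' @param noise_sd additive Gaussian noise sd in intensity units.
#' @param pose a [rigid_transform()] mapping micro-CT world coordinates to
#'   CBCT world coordinates.
#' @param seed integer seed for the noise.
#' @return A [volume3d()] on the CBCT grid.
#' @export
simulate_cbct <- function(uct, target_voxel, psf_sigma = target_voxel,
                          noise_sd = 0, pose = rigid_transform(),
                          seed = 1L) {
  stopifnot(inherits(uct, "volume3d"))
  if (any(target_voxel <= max(uct$voxel_size)))
    stop("target_voxel must be larger than the source voxel size")
  arr <- uct$data
  if (psf_sigma > 0) {
    for (ax in 0:2) {
      sig <- psf_sigma / uct$voxel_size[ax + 1]
      rad <- max(1L, ceiling(3 * sig))
      k <- exp(-0.5 * ((-rad):rad / sig)^2)
      k <- k / sum(k)
      arr <- cpp_convolve_axis(arr, k, ax)
    }
  }
  blurred <- volume3d(arr, uct$voxel_size, uct$origin)
  # output grid: pose-transformed bounding box of the source, padded
  d <- dim(uct$data)
  corners <- as.matrix(expand.grid(c(1, d[1]), c(1, d[2]), c(1, d[3])))
  wc <- apply_transform(pose, voxel_to_world(uct, corners))
  lo <- apply(wc, 2, min) - target_voxel
  hi <- apply(wc, 2, max) + target_voxel
  out_dim <- pmax(1L, as.integer(ceiling((hi - lo) / target_voxel)))
  out <- pullback_resample(blurred, pose, out_dim,
                           rep_len(target_voxel, 3L), lo, mode = "linear")
  if (noise_sd > 0) {
    set.seed(seed)
    out$data <- out$data + rnorm(length(out$data), sd = noise_sd)
  }
  out
}

#' Degrade a ground-truth mask into a manual-annotation surrogate
#'
#' Emulates the systematic behaviour of contrast-limited manual contouring:
#' morphological dilation (over-estimated boundaries) followed by seeded
#' random perturbation of boundary voxels. With zero jitter the output is a
#' superset of the input, so recall against the original mask is 1 while
#' precision drops.
#'
#' @param gt a [binary_mask()].
#' @param dilate_voxels non-negative integer dilation amount
#'   (26-neighbourhood box per step).
#' @param boundary_jitter_sd boundary perturbation scale in voxels; each
#'   voxel in the one-voxel boundary shell is flipped with probability
#'   `min(0.45, boundary_jitter_sd / 2)`.
#' @param seed integer seed.
#' @return A degraded [binary_mask()] on the same grid; always contains the
#'   one-voxel-eroded core of `gt`.
#' @export
degrade_labels <- function(gt, dilate_voxels = 1L, boundary_jitter_sd = 0,
                           seed = 1L) {
  stopifnot(is_binary_mask(gt))
  if (dilate_voxels < 0) stop("dilate_voxels must be >= 0")
  d <- dim(gt$data)
  m <- as.integer(gt$data)
  if (dilate_voxels > 0)
    m <- cpp_dilate(m, d, as.integer(dilate_voxels), 26L)
  if (boundary_jitter_sd > 0) {
    p <- min(0.45, boundary_jitter_sd / 2)
    inner <- cpp_surface_voxels(m, d) == 1L
    outer <- (cpp_dilate(m, d, 1L, 26L) == 1L) & (m == 0L)
    core <- as.integer(gt$data) == 1L &
      !(cpp_surface_voxels(as.integer(gt$data), d) == 1L)
    set.seed(seed)
    shell <- which(inner | outer)
    flip <- shell[runif(length(shell)) < p]
    m[flip] <- 1L - m[flip]
    m[core] <- 1L                     # never break the eroded core
  }
  binary_mask(array(as.numeric(m), d), gt$voxel_size, gt$origin)
}

#' Generate a reproducible cohort of paired micro-CT/CBCT phantoms
#'
#' Draws per-tooth specs from seeded parameter ranges (root length, radii,
#' curvature, accessory-canal and isthmus probability), renders each tooth
#' at micro-CT resolution, and simulates its CBCT acquisition under a
#' random rigid pose (rotations up to 10 degrees, translations up to 1 mm).
#'
#' @param n_sr,n_m numbers of single-rooted and molar phantoms.
#' @param voxel CBCT voxel size in mm (0.2 or 0.08).
#' @param seed integer seed; the full cohort is reproducible.
#' @param uct_voxel micro-CT voxel size in mm.
#' @return A list of `phantom_pair` objects, each with fields `spec`, `uct`,
#'   `tooth_gt`, `canal_gt`, `cbct`, `pose`.
#' @export
generate_cohort <- function(n_sr, n_m = 0L, voxel = 0.08, seed = 1L,
                            uct_voxel = 0.03) {
  n_sr <- as.integer(n_sr); n_m <- as.integer(n_m)
  if (n_sr < 0L || n_m < 0L) stop("cohort sizes must be non-negative")
  n <- n_sr + n_m
  if (n == 0L) return(list())
  set.seed(seed)
  sub_seeds <- sample.int(2^30, 3L * n)
  pairs <- vector("list", n)
  for (t in seq_len(n)) {
    is_m <- t > n_sr
    set.seed(sub_seeds[3L * t - 2L])
    spec <- phantom_spec(
      tooth_class = if (is_m) "M" else "SR",
      n_roots = if (is_m) sample(2:3, 1) else 1L,
      root_length = runif(1, 3.5, 5.5),
      crown_radius = runif(1, 1.3, 1.8),
      canal_radius_coronal = runif(1, 0.3, 0.45),
      canal_radius_apical = runif(1, 0.12, 0.18),
      canal_curvature = runif(1, 0, 0.6),
      accessory_canal = runif(1) < 0.3,
      accessory_level = runif(1, 0.2, 0.4),
      isthmus = is_m && runif(1) < 0.5,
      c_shaped = is_m && runif(1) < 0.2,
      uct_voxel = uct_voxel,
      seed = sub_seeds[3L * t - 1L])
    tooth <- generate_tooth(spec)
    set.seed(sub_seeds[3L * t])
    pose <- rigid_transform(euler_rotation(runif(3, -5.7, 5.7)),
                            runif(3, -0.8, 0.8))
    dentin <- spec$intensities$dentin
    cbct <- simulate_cbct(tooth$uct, target_voxel = voxel,
                          psf_sigma = voxel, noise_sd = 0.05 * dentin,
                          pose = pose, seed = sub_seeds[3L * t])
    pairs[[t]] <- structure(
      list(spec = spec, uct = tooth$uct, tooth_gt = tooth$tooth_gt,
           canal_gt = tooth$canal_gt, cbct = cbct, pose = pose),
      class = "phantom_pair")
  }
  pairs
}
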