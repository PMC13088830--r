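#' Threshold a micro-CT volume into tooth and canal masks
#'
#' Hard mineralized tissue is brighter than both air and the canal
#' contents, so a single global threshold recovers the tooth solid. The
#' procedure is: threshold, keep the largest connected component
#' (26-connectivity), then classify cavities: connected components of the
#' complement that do not touch the volume border are interior cavities and
#' form the root canal system. The returned tooth mask includes the canal
#' space.
#'
#' @param uct a [volume3d()].
#' @param method `"otsu"` for a global Otsu cut, or `"global"` with an
#'   explicit `value`.
#' @param value threshold intensity when `method = "global"`.
#' @return A list with [binary_mask()]s `tooth` (solid including canal
#'   space) and `canal` (interior cavities only).
#' @export
threshold_uct <- function(uct, method = c("otsu", "global"), value = NULL) {
  method <- match.arg(method)
  thr <- if (method == "global") {
    if (is.null(value)) stop("method = \"global\" requires `value`")
    value
  } else otsu_threshold(uct)
  d <- dim(uct$data)
  solid <- as.integer(uct$data >= thr)
  if (sum(solid) == 0L) stop("threshold ", thr, " yields an empty mask")
  labs <- cpp_label_components(solid, d, 26L)
  nc <- attr(labs, "n_components")
  if (nc > 1L) {
    sizes <- tabulate(labs[labs > 0L], nbins = nc)
    solid <- as.integer(labs == which.max(sizes))
  }
  # cavities: background components not touching the border
  bg <- as.integer(solid == 0L)
  bl <- cpp_label_components(bg, d, 6L)
  nb <- attr(bl, "n_components")
  bl_arr <- array(bl, d)
  border_labels <- unique(c(bl_arr[c(1, d[1]), , ], bl_arr[, c(1, d[2]), ],
                            bl_arr[, , c(1, d[3])]))
  canal <- as.integer(bl > 0L & !(bl %in% border_labels))
  tooth <- as.integer(solid | canal)
  list(tooth = binary_mask(array(as.numeric(tooth), d), uct$voxel_size,
                           uct$origin),
       canal = binary_mask(array(as.numeric(canal), d), uct$voxel_size,
                           uct$origin))
}

#' Extract a surface point cloud from a mask
#'
#' Surface voxels are foreground voxels with at least one face-adjacent
#' background neighbour (out-of-bounds counts as background); their world
#' coordinates (voxel centers, mm) are returned, uniformly subsampled to at
#' most `max_points` with the given seed.
#'
#' @param mask non-empty [binary_mask()].
#' @param max_points maximum number of points returned.
#' @param seed integer seed for the subsampling.
#' @return An n-by-3 matrix of world coordinates.
#' @export
extract_surface_points <- function(mask, max_points = 2000L, seed = 1L) {
  stopifnot(is_binary_mask(mask))
  d <- dim(mask$data)
  surf <- cpp_surface_voxels(as.integer(mask$data), d)
  idx <- which(surf == 1L)
  if (length(idx) == 0L) stop("empty mask: no surface points")
  if (length(idx) > max_points) {
    set.seed(seed)
    idx <- sort(sample(idx, max_points))
  }
  voxel_to_world(mask, arrayInd(idx, d))
}

check_cloud <- function(pts, name) {
  if (nrow(pts) < 3L)
    stop(name, " cloud needs at least 3 points, got ", nrow(pts))
  s <- svd(sweep(pts, 2, colMeans(pts)))$d
  if (s[2] < 1e-9 * max(s[1], 1e-12))
    stop(name, " cloud is degenerate (collinear or coincident points)")
  invisible(TRUE)
}

# closed-form least-squares rigid alignment (SVD of the cross-covariance,
# determinant-corrected)
kabsch <- function(moving, fixed) {
  cm <- colMeans(moving); cf <- colMeans(fixed)
  H <- crossprod(sweep(moving, 2, cm), sweep(fixed, 2, cf))
  s <- svd(H)
  D <- diag(c(1, 1, sign(det(s$v %*% t(s$u)))))
  R <- s$v %*% D %*% t(s$u)
  rigid_transform(R, cf - as.numeric(R %*% cm))
}

#' Rigid ICP point-cloud registration
#'
#' Iterative closest point with trimming: at each iteration, every moving
#' point is matched to its nearest fixed point, the worst `trim_fraction`
#' of matches by distance is discarded, and the least-squares rigid
#' alignment of the retained pairs is solved in closed form (SVD of the
#' cross-covariance, determinant-corrected). Initialization aligns the
#' cloud centroids. Iteration stops when the RMS residual improves by less
#' than `tol`, when it would increase (the previous transform is kept), or
#' at `max_iter`. Non-convergence is reported through the residual, not an
#' error.
#'
#' @param moving,fixed n-by-3 point matrices (world mm); at least 3
#'   non-collinear points each.
#' @param max_iter maximum number of iterations.
#' @param tol RMS improvement (mm) below which iteration stops.
#' @param trim_fraction fraction of worst matches discarded per iteration.
#' @param init_rotations_deg coarse initial rotations about the z
#'   (tooth-axis) direction tried in turn; the start with the lowest final
#'   residual wins. Near-axially-symmetric shapes make the z rotation a
#'   multi-basin problem, and a single centroid start can settle in the
#'   wrong basin.
#' @return A list with `transform` (the [rigid_transform()] mapping moving
#'   to fixed), `rms` (final trimmed RMS residual in mm), `residuals`
#'   (per-iteration RMS log of the winning start, non-increasing), and
#'   `iterations`.
#' @export
icp_register <- function(moving, fixed, max_iter = 100L, tol = 1e-4,
                         trim_fraction = 0.1,
                         init_rotations_deg = c(0, 90, 180, 270)) {
  moving <- matrix(moving, ncol = 3); fixed <- matrix(fixed, ncol = 3)
  check_cloud(moving, "moving"); check_cloud(fixed, "fixed")
  n_keep <- max(3L, floor(nrow(moving) * (1 - trim_fraction)))
  cm <- colMeans(moving); cf <- colMeans(fixed)
  run_from <- function(transform) {
    residuals <- numeric(0)
    best_rms <- Inf
    best_transform <- transform
    for (it in seq_len(max_iter)) {
      cur <- apply_transform(transform, moving)
      nn <- cpp_nn_match(cur, fixed)
      keep <- order(nn$distance)[seq_len(n_keep)]
      rms <- sqrt(mean(nn$distance[keep]^2))
      if (rms > best_rms) break        # keep the previous (better) transform
      residuals <- c(residuals, rms)
      improved <- best_rms - rms
      best_rms <- rms
      best_transform <- transform
      if (improved < tol && it > 1L) break
      transform <- kabsch(moving[keep, , drop = FALSE],
                          fixed[nn$index[keep], , drop = FALSE])
    }
    list(transform = best_transform, rms = best_rms, residuals = residuals,
         iterations = length(residuals))
  }
  best <- NULL
  for (ang in init_rotations_deg) {
    R0 <- euler_rotation(c(0, 0, ang))
    init <- rigid_transform(R0, cf - as.numeric(R0 %*% cm))
    res <- run_from(init)
    if (is.null(best) || res$rms < best$rms) best <- res
  }
  best
}

#' Transfer a mask onto a target grid through a rigid transform
#'
#' For each target voxel center, the world coordinate is pulled back
#' through the inverse transform, the source mask is interpolated as a 0/1
#' field (linear by default, matching the smoothing behaviour of resolution
#' normalization; nearest available), and the result is binarized at 0.5.
#' Non-overlapping grids yield an empty mask.
#'
#' @param uct_mask source [binary_mask()] (micro-CT grid).
#' @param transform [rigid_transform()] mapping source world to target
#'   world.
#' @param target a [volume3d()] defining the output grid.
#' @param mode `"linear"` or `"nearest"`.
#' @return A [binary_mask()] on the target grid.
#' @export
transfer_labels <- function(uct_mask, transform, target,
                            mode = c("linear", "nearest")) {
  mode <- match.arg(mode)
  stopifnot(is_binary_mask(uct_mask), inherits(target, "volume3d"))
  out <- pullback_resample(uct_mask, transform, dim(target$data),
                           target$voxel_size, target$origin,
                           mode = mode, fill = 0)
  binary_mask(array(as.numeric(out$data >= 0.5), dim(out$data)),
              target$voxel_size, target$origin)
}

#' Micro-CT-guided ground-truth labels on a CBCT grid
#'
#' The full label-generation chain for one tooth: threshold the micro-CT
#' into tooth + canal masks, extract the tooth surface, extract the CBCT
#' surface by thresholding the CBCT at its own global Otsu cut, register
#' the micro-CT surface onto the CBCT surface with rigid ICP, and transfer
#' both masks onto the CBCT grid through the estimated transform.
#'
#' @param uct micro-CT [volume3d()].
#' @param cbct CBCT [volume3d()] defining the target grid.
#' @param threshold_value explicit micro-CT threshold; `NULL` for Otsu.
#' @param max_points surface points per cloud for ICP.
#' @param seed seed for surface subsampling.
#' @param ... passed to [icp_register()].
#' @return A list with `tooth` and `canal` [binary_mask()]s on the CBCT
#'   grid, the estimated `transform`, and the ICP `rms` residual (mm).
#' @export
uct_guided_labels <- function(uct, cbct, threshold_value = NULL,
                              max_points = 1500L, seed = 1L, ...) {
  masks <- if (is.null(threshold_value)) threshold_uct(uct, "otsu")
           else threshold_uct(uct, "global", value = threshold_value)
  cb_mask <- binarize(cbct, otsu_threshold(cbct))
  cb_mask <- remove_false_positives(cb_mask, "keep_largest_k", k = 1L)
  moving <- extract_surface_points(masks$tooth, max_points, seed)
  fixed <- extract_surface_points(cb_mask, max_points, seed + 1L)
  reg <- icp_register(moving, fixed, ...)
  list(tooth = transfer_labels(masks$tooth, reg$transform, cbct),
       canal = transfer_labels(masks$canal, reg$transform, cbct),
       transform = reg$transform, rms = reg$rms)
}

#' Ground-truth fidelity across target voxel sizes
#'
#' Quantifies the morphological simplification a mask suffers when carried
#' onto coarser grids: for each target voxel size the mask is transferred
#' at identity pose to that grid, transferred back to the native grid, and
#' compared to the original by Dice. For tube-like canal masks the DSC is
#' non-increasing as the voxel grows; at the native size it is 1.
#'
#' @param uct_mask non-empty [binary_mask()].
#' @param target_voxels numeric vector of voxel sizes in mm.
#' @return A data frame with columns `target_voxel` and `dsc`.
#' @export
groundtruth_fidelity <- function(uct_mask, target_voxels) {
  stopifnot(is_binary_mask(uct_mask))
  if (mask_count(uct_mask) == 0) stop("empty mask")
  id <- rigid_transform()
  dsc <- vapply(target_voxels, function(tv) {
    coarse_grid <- resample_volume(uct_mask, tv, mode = "nearest")
    coarse <- transfer_labels(uct_mask, id, coarse_grid)
    back <- transfer_labels(coarse, id, uct_mask)
    overlap_metrics(uct_mask, back)$dsc
  }, numeric(1))
  data.frame(target_voxel = target_voxels, dsc = dsc)
}
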