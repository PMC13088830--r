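#' 3D scalar volume with voxel geometry
#'
#' A `volume3d` is the carrier for all image data in canalseg: micro-CT and
#' CBCT renderings, probability maps, and (via [binary_mask()]) segmentation
#' masks. Data are stored as a numeric 3D array in R's column-major `(x, y,
#' z)` order, so `vol$data[, , k]` is the k-th axial plane. Geometry follows
#' the voxel-center convention: the world coordinate (mm) of 1-based index
#' `(i, j, k)` is `origin + (c(i, j, k) - 1) * voxel_size`.
#'
#' @param data numeric 3D array.
#' @param voxel_size voxel edge length(s) in mm; scalar or length-3, all > 0.
#' @param origin world position (mm) of the center of voxel `(1, 1, 1)`.
#' @return An object of class `volume3d` with fields `data`, `voxel_size`,
#'   `origin`.
#' @examples
#' v <- volume3d(array(0, c(8, 8, 4)), voxel_size = 0.2)
#' dim(v$data)
#' @export
volume3d <- function(data, voxel_size, origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array, got dimensionality ",
         length(dim(data)))
  if (!all(is.finite(data)))
    stop("`data` contains non-finite values")
  voxel_size <- rep_len(as.numeric(voxel_size), 3L)
  if (any(!is.finite(voxel_size)) || any(voxel_size <= 0))
    stop("`voxel_size` components must all be positive and finite")
  origin <- rep_len(as.numeric(origin), 3L)
  if (any(!is.finite(origin))) stop("`origin` must be finite")
  structure(list(data = data, voxel_size = voxel_size, origin = origin),
            class = "volume3d")
}

#' Binary segmentation mask
#'
#' A `binary_mask` is a [volume3d()] whose values are restricted to
#' \{0, 1\}; it represents tooth masks, canal masks, ground truth and
#' predictions.
#'
#' @inheritParams volume3d
#' @return An object of class `c("binary_mask", "volume3d")`.
#' @export
binary_mask <- function(data, voxel_size, origin = c(0, 0, 0)) {
  storage.mode(data) <- "double"
  if (!all(data %in% c(0, 1)))
    stop("mask data must contain only 0 and 1")
  v <- volume3d(data, voxel_size, origin)
  class(v) <- c("binary_mask", "volume3d")
  v
}

is_binary_mask <- function(x) inherits(x, "binary_mask")

#' @export
print.volume3d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<%s> %d x %d x %d voxels @ (%g, %g, %g) mm, origin (%g, %g, %g) mm\n",
              class(x)[1], d[1], d[2], d[3],
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3],
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

#' @export
dim.volume3d <- function(x) dim(x$data)

#' Number of foreground voxels in a mask
#' @param mask a [binary_mask()].
#' @return Integer count of 1-voxels.
#' @export
mask_count <- function(mask) {
  stopifnot(is_binary_mask(mask))
  sum(mask$data)
}

same_grid <- function(a, b, tol = 1e-6) {
  identical(dim(a$data), dim(b$data)) &&
    all(abs(a$voxel_size - b$voxel_size) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

#' Axis-aligned crop box (half-open index intervals)
#'
#' Per-axis half-open 1-based index intervals `[lo, hi)` on a source grid.
#'
#' @param lo,hi integer vectors of length 3; `lo >= 1`, `hi > lo`.
#' @return An object of class `crop_box` with fields `lo` and `hi`.
#' @export
crop_box <- function(lo, hi) {
  lo <- as.integer(rep_len(lo, 3L)); hi <- as.integer(rep_len(hi, 3L))
  if (any(lo < 1L)) stop("crop box `lo` must be >= 1 on every axis")
  if (any(hi <= lo)) stop("crop box must satisfy hi > lo on every axis")
  structure(list(lo = lo, hi = hi), class = "crop_box")
}

#' Read a NIfTI volume
#'
#' Reads a NIfTI-1 file, reorients it to the canonical RAS+ frame, and
#' extracts the voxel size from the affine column norms and the origin from
#' its translation.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return A [volume3d()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop("expected a 3D image, got dimensionality ", length(d))
  RNifti::orientation(img) <- "RAS"
  aff <- RNifti::xform(img)
  if (!all(is.finite(aff))) stop("non-finite affine in ", path)
  voxel <- sqrt(colSums(aff[1:3, 1:3]^2))
  if (any(voxel <= 0) || abs(det(aff[1:3, 1:3])) < 1e-12)
    stop("degenerate (non-invertible) affine in ", path)
  origin <- aff[1:3, 4]
  arr <- array(as.numeric(img), dim = dim(img))
  volume3d(arr, voxel_size = voxel, origin = origin)
}

#' Write a volume as NIfTI
#'
#' Writes RAS+ NIfTI-1 with a diagonal affine whose entries are the voxel
#' size and whose translation is the origin. Masks are stored as unsigned
#' 8-bit, images as 32-bit float (or 16-bit int when integral).
#'
#' @param vol a [volume3d()] or [binary_mask()].
#' @param path output path (`.nii` or `.nii.gz`); parent directory must
#'   exist.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "volume3d"))
  if (!dir.exists(dirname(path)))
    stop("parent directory does not exist: ", dirname(path))
  if (is_binary_mask(vol)) {
    dtype <- "uint8"
    arr <- vol$data
    storage.mode(arr) <- "integer"
  } else {
    arr <- vol$data
    integral <- all(arr == round(arr)) && max(abs(arr)) < 32767
    dtype <- if (integral) "int16" else "float"
    if (integral) storage.mode(arr) <- "integer"
  }
  img <- RNifti::asNifti(arr, datatype = dtype)
  aff <- diag(c(vol$voxel_size, 1))
  aff[1:3, 4] <- vol$origin
  img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Resample a volume to a new isotropic voxel size
#'
#' The output grid covers the same world extent as the input: per axis the
#' output extent is `ceiling(n_in * size_in / size_out)`, and the output
#' origin equals the input origin. Values are obtained by trilinear
#' (`"linear"`) or nearest-neighbour (`"nearest"`) interpolation at the
#' output voxel-center world coordinates; sites outside the input support
#' are filled with the image minimum (background). Nearest mode on a
#' [binary_mask()] returns a [binary_mask()].
#'
#' @param vol a [volume3d()] (or mask).
#' @param target_voxel_size target voxel edge length in mm (> 0), scalar or
#'   length 3.
#' @param mode `"linear"` or `"nearest"`.
#' @return The resampled volume on the new grid.
#' @export
resample_volume <- function(vol, target_voxel_size,
                            mode = c("linear", "nearest")) {
  mode <- match.arg(mode)
  target <- rep_len(as.numeric(target_voxel_size), 3L)
  if (any(!is.finite(target)) || any(target <= 0))
    stop("`target_voxel_size` must be positive")
  n_in <- dim(vol$data)
  n_out <- as.integer(ceiling(n_in * vol$voxel_size / target - 1e-9))
  n_out <- pmax(n_out, 1L)
  # 0-based source index of output voxel i0: (origin_out + i0*target -
  # origin_in) / voxel_in; origins coincide.
  A <- diag(target / vol$voxel_size)
  b <- c(0, 0, 0)
  fill <- min(vol$data)
  out <- cpp_affine_resample(vol$data, n_out, A, b, mode == "linear", fill)
  if (is_binary_mask(vol) && mode == "nearest")
    binary_mask(out, voxel_size = target, origin = vol$origin)
  else
    volume3d(out, voxel_size = target, origin = vol$origin)
}

#' Crop a volume to a box
#'
#' @param vol a [volume3d()] or [binary_mask()].
#' @param box a [crop_box()]; must lie within the volume extents.
#' @return The cropped volume; origin shifted by `(lo - 1) * voxel_size`.
#' @export
crop_to_box <- function(vol, box) {
  stopifnot(inherits(vol, "volume3d"), inherits(box, "crop_box"))
  d <- dim(vol$data)
  if (any(box$hi - 1L > d))
    stop("crop box exceeds volume extents (", paste(d, collapse = "x"), ")")
  arr <- vol$data[box$lo[1]:(box$hi[1] - 1L),
                  box$lo[2]:(box$hi[2] - 1L),
                  box$lo[3]:(box$hi[3] - 1L), drop = FALSE]
  origin <- vol$origin + (box$lo - 1L) * vol$voxel_size
  if (is_binary_mask(vol)) binary_mask(arr, vol$voxel_size, origin)
  else volume3d(arr, vol$voxel_size, origin)
}

#' Tooth-centred crop box
#'
#' Builds the standardized training crop: an in-plane window of exactly
#' `axial_size` by `axial_size` voxels centred on the mask centroid (clamped
#' to the grid), with a z-range equal to the mask's z bounding box padded by
#' `z_margin` slices and clamped. The crop depth thus follows the tooth
#' length while axial sizes stay fixed.
#'
#' @param tooth_mask non-empty [binary_mask()].
#' @param axial_size in-plane window size in voxels; must be at least the
#'   mask's in-plane bounding width.
#' @param z_margin extra slices added above and below the mask.
#' @return A [crop_box()].
#' @export
tooth_crop_box <- function(tooth_mask, axial_size, z_margin = 4L) {
  stopifnot(is_binary_mask(tooth_mask))
  idx <- which(tooth_mask$data == 1)
  if (length(idx) == 0L) stop("empty mask: cannot place a crop box")
  d <- dim(tooth_mask$data)
  ijk <- arrayInd(idx, d)
  rng <- apply(ijk, 2, range)
  widths <- rng[2, 1:2] - rng[1, 1:2] + 1L
  if (axial_size < max(widths))
    stop("axial_size (", axial_size, ") smaller than the mask's in-plane ",
         "extent (", max(widths), ")")
  centroid <- colMeans(ijk)
  lo <- integer(3)
  for (ax in 1:2) {
    l <- as.integer(round(centroid[ax] - axial_size / 2))
    l <- max(1L, min(l, d[ax] - as.integer(axial_size) + 1L))
    if (l < 1L) l <- 1L
    lo[ax] <- l
  }
  zlo <- max(1L, rng[1, 3] - as.integer(z_margin))
  zhi <- min(d[3], rng[2, 3] + as.integer(z_margin))
  crop_box(lo = c(lo[1], lo[2], zlo),
           hi = c(lo[1] + as.integer(axial_size),
                  lo[2] + as.integer(axial_size), zhi + 1L))
}

#' Threshold a volume into a binary mask
#'
#' Voxels with value `>= threshold` become foreground (ties go to
#' foreground).
#'
#' @param vol a [volume3d()].
#' @param threshold scalar threshold.
#' @return A [binary_mask()] on the same grid.
#' @export
binarize <- function(vol, threshold) {
  stopifnot(inherits(vol, "volume3d"))
  arr <- array(as.numeric(vol$data >= threshold), dim = dim(vol$data))
  binary_mask(arr, vol$voxel_size, vol$origin)
}

#' World coordinates of voxel indices
#'
#' @param vol a [volume3d()].
#' @param ijk n-by-3 matrix of 1-based voxel indices.
#' @return n-by-3 matrix of world coordinates (mm), voxel-center convention.
#' @export
voxel_to_world <- function(vol, ijk) {
  ijk <- matrix(ijk, ncol = 3)
  sweep(sweep(ijk - 1, 2, vol$voxel_size, "*"), 2, vol$origin, "+")
}

#' Global Otsu threshold of a volume
#'
#' Maximizes between-class variance on a 256-bin histogram of the full 3D
#' intensity distribution (a single global cut, not per-slice).
#'
#' @param vol a [volume3d()].
#' @param levels number of histogram bins.
#' @return The threshold on the intensity scale of `vol`.
#' @export
otsu_threshold <- function(vol, levels = 256L) {
  x <- as.numeric(vol$data)
  r <- range(x)
  if (diff(r) == 0) stop("constant volume: Otsu threshold undefined")
  h <- tabulate(pmin(levels, 1L + floor((x - r[1]) / diff(r) * levels)),
                nbins = levels)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(levels))
  mu_t <- mu[levels]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  k <- which.max(sigma_b)
  r[1] + k / levels * diff(r)
}
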