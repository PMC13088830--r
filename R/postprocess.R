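#' Connected components of a binary mask
#'
#' Flood-fill labelling under 6- or 26-connectivity, with per-component
#' voxel counts, world-space centroids and z-extents — the information
#' needed to separate predicted voxels into individual objects and reason
#' about false positives.
#'
#' @param mask a [binary_mask()].
#' @param connectivity 6 (faces) or 26 (faces, edges, corners; default).
#' @return A list of class `component_set` with `labels` (integer array, 0
#'   background), `n`, and `components` (data frame: `label`, `size`,
#'   world `centroid_x/y/z`, `z_min`, `z_max`).
#' @export
connected_components <- function(mask, connectivity = 26L) {
  stopifnot(is_binary_mask(mask), connectivity %in% c(6L, 26L))
  d <- dim(mask$data)
  labs <- cpp_label_components(as.integer(mask$data), d,
                               as.integer(connectivity))
  n <- attr(labs, "n_components")
  labels <- array(as.integer(labs), d)
  if (n == 0L) {
    comps <- data.frame(label = integer(0), size = integer(0),
                        centroid_x = numeric(0), centroid_y = numeric(0),
                        centroid_z = numeric(0), z_min = numeric(0),
                        z_max = numeric(0))
  } else {
    idx <- which(labels > 0L)
    ijk <- arrayInd(idx, d)
    lab <- labels[idx]
    w <- voxel_to_world(mask, ijk)
    comps <- data.frame(
      label = seq_len(n),
      size = tabulate(lab, nbins = n),
      centroid_x = vapply(split(w[, 1], lab), mean, numeric(1)),
      centroid_y = vapply(split(w[, 2], lab), mean, numeric(1)),
      centroid_z = vapply(split(w[, 3], lab), mean, numeric(1)),
      z_min = vapply(split(w[, 3], lab), min, numeric(1)),
      z_max = vapply(split(w[, 3], lab), max, numeric(1)))
    rownames(comps) <- NULL
  }
  structure(list(labels = labels, n = n, components = comps,
                 voxel_size = mask$voxel_size, origin = mask$origin),
            class = "component_set")
}

#' Remove false-positive components from a predicted mask
#'
#' Separates the prediction into connected objects and zeroes those failing
#' the chosen policy:
#' * `keep_largest_k`: keep only the `k` largest components;
#' * `min_size`: keep components with at least `min_voxels` voxels;
#' * `keep_in_region`: keep components whose world centroid lies inside a
#'   region mask (e.g. the tooth below the cervical plane, where true canals
#'   live and coronal false positives do not).
#'
#' The output is always a subset of the input, and applying the same policy
#' twice equals applying it once.
#'
#' @param mask predicted [binary_mask()].
#' @param policy one of `"keep_largest_k"`, `"min_size"`,
#'   `"keep_in_region"`.
#' @param k number of components kept by `keep_largest_k` (>= 1).
#' @param min_voxels minimum component size for `min_size`.
#' @param region non-empty [binary_mask()] on the same grid for
#'   `keep_in_region`.
#' @param connectivity 6 or 26.
#' @return The cleaned [binary_mask()].
#' @export
remove_false_positives <- function(mask,
                                   policy = c("keep_largest_k", "min_size",
                                              "keep_in_region"),
                                   k = 1L, min_voxels = 1L, region = NULL,
                                   connectivity = 26L) {
  policy <- match.arg(policy)
  cs <- connected_components(mask, connectivity)
  if (cs$n == 0L) return(mask)
  comps <- cs$components
  keep <- switch(policy,
    keep_largest_k = {
      if (k < 1L) stop("k must be >= 1")
      comps$label[order(comps$size, decreasing = TRUE)[seq_len(min(k, cs$n))]]
    },
    min_size = comps$label[comps$size >= min_voxels],
    keep_in_region = {
      if (is.null(region) || !is_binary_mask(region))
        stop("keep_in_region requires a `region` mask")
      if (mask_count(region) == 0) stop("empty region mask")
      if (!same_grid(mask, region)) stop("region is on a different grid")
      cen <- cbind(comps$centroid_x, comps$centroid_y, comps$centroid_z)
      ijk <- round(sweep(sweep(cen, 2, mask$origin), 2, mask$voxel_size,
                         "/")) + 1
      d <- dim(mask$data)
      inside <- vapply(seq_len(nrow(ijk)), function(r) {
        v <- pmin(pmax(ijk[r, ], 1), d)
        region$data[v[1], v[2], v[3]] == 1
      }, logical(1))
      comps$label[inside]
    })
  out <- array(as.numeric(cs$labels %in% keep & cs$labels > 0L),
               dim(mask$data))
  binary_mask(out, mask$voxel_size, mask$origin)
}

#' Radicular region surrogate for false-positive filtering
#'
#' Builds the default `keep_in_region` region: the given tooth mask
#' restricted to slices below its widest axial cross-section (a
#' cervical-plane surrogate). Coronal false positives in the dentin under
#' the enamel land above this plane; root canals lie below it.
#'
#' @param tooth_mask a non-empty [binary_mask()]; the z axis must run
#'   apex-to-crown.
#' @return A [binary_mask()] on the same grid.
#' @export
radicular_region <- function(tooth_mask) {
  stopifnot(is_binary_mask(tooth_mask))
  if (mask_count(tooth_mask) == 0) stop("empty tooth mask")
  areas <- apply(tooth_mask$data, 3, sum)
  cervical <- which.max(areas)
  out <- tooth_mask$data
  if (cervical < dim(out)[3]) out[, , (cervical + 1L):dim(out)[3]] <- 0
  binary_mask(out, tooth_mask$voxel_size, tooth_mask$origin)
}
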