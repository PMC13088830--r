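#' Voxel-overlap metrics between ground truth and segmentation
#'
#' Computes the three standard overlap metrics from exact voxel counts:
#' \deqn{DSC = 2|V_{gt} \cap V_{seg}| / (|V_{gt}| + |V_{seg}|)}
#' \deqn{SEN = |V_{gt} \cap V_{seg}| / |V_{gt}|}
#' \deqn{IOU = |V_{gt} \cap V_{seg}| / |V_{gt} \cup V_{seg}|}
#' where \eqn{V_{gt}} and \eqn{V_{seg}} are the foreground voxel sets.
#' Degenerate cases: if both masks are empty all metrics are 1 by
#' convention; if only the ground truth is empty, SEN is undefined and
#' reported as 0 with `gt_empty = TRUE`.
#'
#' @param gt,seg [binary_mask()]s on identical grids.
#' @return A list of class `metric_report` with `dsc`, `sen`, `iou`,
#'   `counts` (`n_gt`, `n_seg`, `n_intersection`, `n_union`) and
#'   `gt_empty`.
#' @export
overlap_metrics <- function(gt, seg) {
  stopifnot(is_binary_mask(gt), is_binary_mask(seg))
  if (!same_grid(gt, seg))
    stop("masks are on different grids (dims/voxel size/origin differ)")
  n_gt <- as.integer(sum(gt$data))
  n_seg <- as.integer(sum(seg$data))
  n_int <- as.integer(sum(gt$data * seg$data))
  n_uni <- n_gt + n_seg - n_int
  gt_empty <- FALSE
  if (n_gt == 0 && n_seg == 0) {
    dsc <- sen <- iou <- 1
  } else {
    dsc <- 2 * n_int / (n_gt + n_seg)
    iou <- n_int / n_uni
    if (n_gt == 0) { sen <- 0; gt_empty <- TRUE } else sen <- n_int / n_gt
  }
  structure(list(dsc = dsc, sen = sen, iou = iou,
                 counts = c(n_gt = n_gt, n_seg = n_seg,
                            n_intersection = n_int, n_union = n_uni),
                 gt_empty = gt_empty),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("DSC %.4f  SEN %.4f  IOU %.4f  (|gt| %d, |seg| %d)\n",
              x$dsc, x$sen, x$iou, x$counts["n_gt"], x$counts["n_seg"]))
  invisible(x)
}

#' Signed surface deviation between a prediction and the ground truth
#'
#' For every predicted-surface voxel center, the distance to the nearest
#' ground-truth-surface voxel center is computed (point-cloud to
#' point-cloud), signed positive when the predicted point lies outside the
#' ground-truth solid and negative inside. The display band (e.g. +-0.5 mm
#' for tooth surfaces, +-0.2 mm for canals) is a reporting range only: no
#' points are discarded.
#'
#' @param pred,gt non-empty [binary_mask()]s on identical grids.
#' @param band half-width of the reporting band in mm.
#' @return A list of class `deviation_report` with `distances` (signed mm,
#'   one per predicted surface point), `mean`, `sd`, `pct_within_band`, and
#'   `band`.
#' @export
surface_deviation <- function(pred, gt, band = 0.5) {
  stopifnot(is_binary_mask(pred), is_binary_mask(gt))
  if (!same_grid(pred, gt)) stop("masks are on different grids")
  if (mask_count(pred) == 0 || mask_count(gt) == 0)
    stop("surface deviation requires two non-empty masks")
  d <- dim(pred$data)
  ps_idx <- which(cpp_surface_voxels(as.integer(pred$data), d) == 1L)
  gs_idx <- which(cpp_surface_voxels(as.integer(gt$data), d) == 1L)
  ps_ijk <- arrayInd(ps_idx, d)
  pts_p <- voxel_to_world(pred, ps_ijk)
  pts_g <- voxel_to_world(gt, arrayInd(gs_idx, d))
  nn <- cpp_nn_match(pts_p, pts_g)
  inside <- gt$data[ps_idx] == 1
  dist <- nn$distance * ifelse(inside, -1, 1)
  structure(list(distances = dist, mean = mean(dist), sd = sd(dist),
                 pct_within_band = 100 * mean(abs(dist) <= band),
                 band = band),
            class = "deviation_report")
}

#' @export
print.deviation_report <- function(x, ...) {
  cat(sprintf("signed surface deviation: %.3f +/- %.3f mm; %.1f%% within +/-%.2f mm\n",
              x$mean, x$sd, x$pct_within_band, x$band))
  invisible(x)
}

#' Tabulate a paired comparison of two sets of metric reports
#'
#' Summarizes two arms (e.g. micro-CT-guided vs manual-label-based) as
#' per-metric means and standard deviations plus the mean paired
#' difference (a - b). No hypothesis tests are computed.
#'
#' @param reports_a,reports_b equal-length lists of `metric_report`s.
#' @param paired logical; kept for interface clarity (differences are
#'   computed pairwise either way over equal-length lists).
#' @return A data frame with one row per metric: `mean_a`, `sd_a`,
#'   `mean_b`, `sd_b`, `mean_diff`.
#' @export
compare_arms <- function(reports_a, reports_b, paired = TRUE) {
  if (length(reports_a) != length(reports_b))
    stop("report lists have different lengths (",
         length(reports_a), " vs ", length(reports_b), ")")
  grab <- function(reports, m) vapply(reports, `[[`, numeric(1), m)
  rows <- lapply(c("dsc", "sen", "iou"), function(m) {
    a <- grab(reports_a, m); b <- grab(reports_b, m)
    data.frame(metric = m, mean_a = mean(a), sd_a = sd(a),
               mean_b = mean(b), sd_b = sd(b), mean_diff = mean(a - b))
  })
  do.call(rbind, rows)
}
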