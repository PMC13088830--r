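#' Training hyperparameters for one cascade stage
#'
#' Defaults target full-scale training (Adam at learning rate 1e-3, 400
#' epochs, random rotation and clipping augmentation); the desk-scale
#' acceptance profile overrides `epochs` downward.
#'
#' @param epochs number of passes over the training slices (>= 1).
#' @param learning_rate initial Adam learning rate.
#' @param batch_size slices per optimizer step.
#' @param rotation_deg in-plane augmentation rotation range (+- degrees).
#' @param crop_fraction_range random-crop fraction range in (0, 1].
#' @param dice_weight weight of the soft-Dice addend to the
#'   deep-supervised binary cross-entropy loss.
#' @param slice_stride train on every `slice_stride`-th axial slice
#'   (1 = all slices); inference always uses every slice.
#' @param seed integer seed controlling initialization, shuffling and
#'   augmentation.
#' @param stage `"TS"` (tooth) or `"RCS"` (root canal).
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs = 400L, learning_rate = 1e-3,
                         batch_size = 8L, rotation_deg = 15,
                         crop_fraction_range = c(0.9, 1.0),
                         dice_weight = 0.5, slice_stride = 1L, seed = 1L,
                         stage = c("TS", "RCS")) {
  stage <- match.arg(stage)
  if (epochs < 1L) stop("epochs must be >= 1")
  if (learning_rate <= 0) stop("learning_rate must be positive")
  if (any(crop_fraction_range <= 0) || any(crop_fraction_range > 1))
    stop("crop_fraction_range must lie in (0, 1]")
  if (slice_stride < 1L) stop("slice_stride must be >= 1")
  structure(list(epochs = as.integer(epochs), learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 rotation_deg = rotation_deg,
                 crop_fraction_range = crop_fraction_range,
                 dice_weight = dice_weight,
                 slice_stride = as.integer(slice_stride),
                 seed = as.integer(seed), stage = stage),
            class = "train_config")
}

#' Attach micro-CT-guided labels to a phantom cohort
#'
#' Runs [uct_guided_labels()] for every phantom pair and stores the
#' transferred tooth and canal masks (and the estimated transform) on the
#' pair. The micro-CT threshold defaults to the midpoint of the canal and
#' dentin intensity means of each phantom's spec.
#'
#' @param cohort list of `phantom_pair`s from [generate_cohort()].
#' @param max_points ICP surface points per cloud.
#' @param seed seed for surface subsampling.
#' @return The cohort with `tooth_label`, `canal_label`, `transform`,
#'   `icp_rms` added to each pair.
#' @export
transfer_cohort_labels <- function(cohort, max_points = 1500L, seed = 1L) {
  lapply(cohort, function(pair) {
    ints <- pair$spec$intensities
    lab <- uct_guided_labels(pair$uct, pair$cbct,
                             threshold_value = (ints$canal + ints$dentin) / 2,
                             max_points = max_points, seed = seed)
    pair$tooth_label <- lab$tooth
    pair$canal_label <- lab$canal
    pair$transform <- lab$transform
    pair$icp_rms <- lab$rms
    pair
  })
}

mask_volume_to <- function(vol, mask, background = min(vol$data)) {
  out <- vol
  out$data[mask$data == 0] <- background
  out
}

#' Build training pairs for one cascade stage
#'
#' TS pairs are (CBCT crop, tooth label crop); RCS pairs mask the CBCT crop
#' to the tooth label region (outside voxels set to the background value,
#' the per-volume minimum) and pair it with the canal label crop. The crop
#' is the standardized tooth-centred window of [tooth_crop_box()].
#' `label_source = "degraded"` replaces the training labels by their
#' [degrade_labels()] surrogate (manual-annotation arm); evaluation against
#' test-set ground truth always uses the micro-CT-transferred labels.
#'
#' @param cohort labelled cohort from [transfer_cohort_labels()].
#' @param stage `"TS"` or `"RCS"`.
#' @param label_source `"uct_guided"` or `"degraded"`.
#' @param axial_size in-plane crop size (voxels); use a multiple of the
#'   network's downsampling factor.
#' @param z_margin crop padding in slices.
#' @param dilate_voxels,boundary_jitter_sd,degrade_seed parameters of the
#'   degraded arm.
#' @return A list of `training_pair`s: `image`, `label`, `tooth_mask`
#'   (RCS), `tooth_id`, `group`, `voxel`.
#' @export
make_pairs <- function(cohort, stage = c("TS", "RCS"),
                       label_source = c("uct_guided", "degraded"),
                       axial_size = 48L, z_margin = 4L,
                       dilate_voxels = 1L, boundary_jitter_sd = 0,
                       degrade_seed = 1L) {
  stage <- match.arg(stage)
  label_source <- match.arg(label_source)
  lapply(seq_along(cohort), function(t) {
    pair <- cohort[[t]]
    if (is.null(pair$tooth_label))
      stop("cohort has no transferred labels; run transfer_cohort_labels()")
    tooth_lab <- pair$tooth_label
    canal_lab <- pair$canal_label
    if (label_source == "degraded") {
      tooth_lab <- degrade_labels(tooth_lab, dilate_voxels,
                                  boundary_jitter_sd, degrade_seed + t)
      canal_lab <- degrade_labels(canal_lab, dilate_voxels,
                                  boundary_jitter_sd, degrade_seed + t)
      canal_lab$data <- canal_lab$data * tooth_lab$data
    }
    box <- tooth_crop_box(pair$tooth_label, axial_size, z_margin)
    img <- crop_to_box(pair$cbct, box)
    tooth_crop <- crop_to_box(tooth_lab, box)
    if (stage == "TS") {
      list(image = img, label = tooth_crop, tooth_mask = NULL,
           tooth_id = t, group = pair$spec$tooth_class,
           voxel = pair$cbct$voxel_size[1])
    } else {
      canal_crop <- crop_to_box(canal_lab, box)
      canal_crop$data <- canal_crop$data * tooth_crop$data
      list(image = mask_volume_to(img, tooth_crop), label = canal_crop,
           tooth_mask = tooth_crop, tooth_id = t,
           group = pair$spec$tooth_class, voxel = pair$cbct$voxel_size[1])
    }
  })
}

#' Jointly augment a training pair
#'
#' Applies one seeded in-plane rotation and centred random crop (then
#' resize back to the original grid) identically to image and label; the
#' label is re-binarized at 0.5 after interpolation.
#'
#' @param pair a training pair from [make_pairs()].
#' @param rotation_deg_range rotation range (+- degrees).
#' @param crop_fraction_range crop fraction range in (0, 1].
#' @param seed integer seed.
#' @return The augmented pair.
#' @export
augment_pair <- function(pair, rotation_deg_range = 15,
                         crop_fraction_range = c(0.9, 1.0), seed = 1L) {
  set.seed(seed)
  theta <- runif(1, -rotation_deg_range, rotation_deg_range)
  frac <- runif(1, crop_fraction_range[1], crop_fraction_range[2])
  if (theta == 0 && frac == 1) return(pair)
  d <- dim(pair$image$data)
  ctr <- (d[1:2] - 1) / 2
  th <- theta * pi / 180
  R2 <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  # output index -> source index: rotate and zoom about the slice centre
  A <- diag(3)
  A[1:2, 1:2] <- R2 * frac
  b <- c(ctr - (R2 * frac) %*% ctr, 0)
  warp <- function(arr, fill) cpp_affine_resample(arr, d, A, b, TRUE, fill)
  out <- pair
  out$image$data <- warp(pair$image$data, min(pair$image$data))
  lab <- warp(pair$label$data, 0)
  out$label$data <- array(as.numeric(lab >= 0.5), d)
  if (!is.null(pair$tooth_mask)) {
    tm <- warp(pair$tooth_mask$data, 0)
    out$tooth_mask$data <- array(as.numeric(tm >= 0.5), d)
  }
  out
}

pair_slices <- function(pairs, stride = 1L) {
  imgs <- lapply(pairs, function(p) normalize_minmax(p$image$data))
  idx <- do.call(rbind, lapply(seq_along(pairs), function(i) {
    cbind(pair = i, k = seq(1L, dim(pairs[[i]]$image$data)[3], by = stride))
  }))
  list(imgs = imgs, idx = idx)
}

eval_loss <- function(params, cfg, pairs, dice_weight) {
  sl <- pair_slices(pairs)
  total <- 0
  for (r in seq_len(nrow(sl$idx))) {
    i <- sl$idx[r, 1]; k <- sl$idx[r, 2]
    d <- dim(sl$imgs[[i]])
    x <- array(sl$imgs[[i]][, , k], c(d[1], d[2], 1L))
    y <- pairs[[i]]$label$data[, , k]
    fw <- net_fwd(params, cfg, x)
    total <- total + slice_loss(fw, y, dice_weight)$loss
  }
  total / nrow(sl$idx)
}

#' Train one cascade stage
#'
#' Slice-wise mini-batch optimization with the deep-supervised loss:
#' slices of all training pairs are shuffled each epoch, gradients are
#' accumulated over `batch_size` slices per Adam step, and per-epoch
#' augmented copies of each pair are drawn when augmentation is enabled.
#' The returned model carries the best-validation-loss parameters (best
#' training loss when no validation pairs are given). Fully seeded.
#'
#' @param pairs training pairs from [make_pairs()] (>= 1).
#' @param val_pairs validation pairs (may be empty).
#' @param net_config a [net_config()].
#' @param config a [train_config()].
#' @param verbose print per-epoch losses.
#' @param init optional result of a previous [train_stage()] call to warm
#'   start from (continues the optimizer state and epoch counter).
#' @return A list with `model` ([seg_model][build_model()]), `history`
#'   (data frame: epoch, train_loss, val_loss), and internal warm-start
#'   state.
#' @export
train_stage <- function(pairs, val_pairs = list(), net_config,
                        config = train_config(), verbose = FALSE,
                        init = NULL) {
  if (length(pairs) == 0L) stop("empty training set")
  for (p in pairs) {
    d <- dim(p$image$data)
    if (any(d[1:2] %% net_config$pad_multiple != 0))
      stop("in-plane crop extents must be multiples of ",
           net_config$pad_multiple, " for training (got ",
           d[1], "x", d[2], ")")
  }
  if (is.null(init)) {
    set.seed(config$seed)
    model <- build_model(net_config, seed = config$seed)
    params <- model$params
    state <- adam_init(params)
    history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                          val_loss = numeric(0))
    best <- Inf
    best_params <- params
    ep0 <- 0L
  } else {
    model <- init$model
    params <- init$last_params
    state <- init$opt_state
    history <- init$history
    best <- init$best
    best_params <- init$model$params
    ep0 <- nrow(history)
    set.seed(config$seed + ep0)
  }
  augment <- config$rotation_deg > 0 || config$crop_fraction_range[1] < 1
  for (ep in ep0 + seq_len(config$epochs)) {
    ep_pairs <- if (augment) {
      lapply(seq_along(pairs), function(i)
        augment_pair(pairs[[i]], config$rotation_deg,
                     config$crop_fraction_range,
                     seed = config$seed + 7919L * ep + i))
    } else pairs
    sl <- pair_slices(ep_pairs, config$slice_stride)
    ord <- sample(nrow(sl$idx))
    acc <- NULL
    n_in_batch <- 0L
    ep_loss <- 0
    for (r in ord) {
      i <- sl$idx[r, 1]; k <- sl$idx[r, 2]
      d <- dim(sl$imgs[[i]])
      x <- array(sl$imgs[[i]][, , k], c(d[1], d[2], 1L))
      y <- ep_pairs[[i]]$label$data[, , k]
      fw <- net_fwd(params, net_config, x)
      ls <- slice_loss(fw, y, config$dice_weight)
      ep_loss <- ep_loss + ls$loss
      g <- net_bwd(params, net_config, fw$cache, ls$dlogits)
      acc <- if (is.null(acc)) g else param_map2(`+`, acc, g)
      n_in_batch <- n_in_batch + 1L
      if (n_in_batch == config$batch_size) {
        acc <- param_map(function(x) x / n_in_batch, acc)
        st <- adam_step(params, acc, state, config$learning_rate)
        params <- st$params; state <- st$state
        acc <- NULL; n_in_batch <- 0L
      }
    }
    if (n_in_batch > 0L) {
      acc <- param_map(function(x) x / n_in_batch, acc)
      st <- adam_step(params, acc, state, config$learning_rate)
      params <- st$params; state <- st$state
    }
    train_loss <- ep_loss / nrow(sl$idx)
    val_loss <- if (length(val_pairs) > 0)
      eval_loss(params, net_config, val_pairs, config$dice_weight)
    else NA_real_
    history <- rbind(history, data.frame(epoch = ep, train_loss = train_loss,
                                         val_loss = val_loss))
    crit <- if (is.na(val_loss)) train_loss else val_loss
    if (crit < best) { best <- crit; best_params <- params }
    if (verbose)
      message(sprintf("epoch %d  train %.5f  val %s", ep, train_loss,
                      ifelse(is.na(val_loss), "-", sprintf("%.5f", val_loss))))
  }
  model$params <- best_params
  list(model = model, history = history, opt_state = state,
       last_params = params, best = best)
}

#' Segment the tooth from a CBCT crop
#'
#' Prediction, binarization at 0.5, and largest-connected-component
#' selection. An all-background prediction returns an empty mask with
#' attribute `empty_warning = TRUE` instead of raising.
#'
#' @param model_ts trained TS [seg_model][build_model()].
#' @param cbct_crop CBCT [volume3d()] crop.
#' @return A [binary_mask()] on the crop grid.
#' @export
segment_tooth <- function(model_ts, cbct_crop) {
  prob <- predict_volume(model_ts, cbct_crop)
  m <- binarize(prob, 0.5)
  if (mask_count(m) == 0) {
    attr(m, "empty_warning") <- TRUE
    warning("tooth segmentation is empty")
    return(m)
  }
  remove_false_positives(m, "keep_largest_k", k = 1L)
}

#' Cascaded root-canal segmentation
#'
#' Stage TS segments the tooth; the CBCT crop is masked to the predicted
#' tooth region (outside voxels set to the background value); stage RCS is
#' applied to the masked image; the binarized canal prediction is
#' restricted to the predicted tooth mask (so canal is contained in tooth
#' on every input).
#'
#' @param model_ts,model_rcs trained stage models.
#' @param cbct_crop CBCT [volume3d()] crop.
#' @return A list with `canal` and `tooth` [binary_mask()]s.
#' @export
segment_canal <- function(model_ts, model_rcs, cbct_crop) {
  tooth <- segment_tooth(model_ts, cbct_crop)
  if (mask_count(tooth) == 0) {
    canal <- tooth
    attr(canal, "empty_warning") <- TRUE
    return(list(canal = canal, tooth = tooth))
  }
  masked <- mask_volume_to(cbct_crop, tooth)
  prob <- predict_volume(model_rcs, masked)
  canal <- binarize(prob, 0.5)
  canal$data <- canal$data * tooth$data
  list(canal = canal, tooth = tooth)
}

evaluate_cascade <- function(model_ts, model_rcs, test_pairs_ts,
                             test_pairs_rcs) {
  lapply(seq_along(test_pairs_ts), function(i) {
    seg <- segment_canal(model_ts, model_rcs, test_pairs_ts[[i]]$image)
    list(tooth = overlap_metrics(test_pairs_ts[[i]]$label, seg$tooth),
         canal = overlap_metrics(test_pairs_rcs[[i]]$label, seg$canal))
  })
}

#' Two-arm training comparison (micro-CT-guided vs degraded labels)
#'
#' Trains the full two-stage cascade twice on the same cohort — once with
#' micro-CT-transferred labels and once with the dilation-degraded
#' manual-annotation surrogate — and evaluates both on held-out test
#' phantoms against micro-CT-transferred ground truth. The expected
#' direction mirrors the annotation mechanism: the degraded arm inflates
#' boundaries, gaining sensitivity at the cost of Dice and IoU.
#'
#' @param cohort labelled cohort from [transfer_cohort_labels()].
#' @param n_test number of test phantoms (taken from the cohort tail).
#' @param net_config a [net_config()].
#' @param config a [train_config()] (stage field ignored; both stages are
#'   trained with these settings).
#' @param axial_size,dilate_voxels passed to [make_pairs()].
#' @return A list with per-arm aggregated metric means (`uct`, `degraded`:
#'   dsc/sen/iou averaged over test teeth and both stages), per-arm report
#'   lists, and the [compare_arms()] table.
#' @export
run_arm_experiment <- function(cohort, n_test = 2L, net_config = net_config(),
                               config = train_config(), axial_size = 48L,
                               dilate_voxels = 1L) {
  n <- length(cohort)
  stopifnot(n_test >= 1L, n > n_test)
  train_ids <- seq_len(n - n_test)
  test_ids <- (n - n_test + 1L):n
  arms <- list()
  test_ts <- make_pairs(cohort[test_ids], "TS", "uct_guided",
                        axial_size = axial_size)
  test_rcs <- make_pairs(cohort[test_ids], "RCS", "uct_guided",
                         axial_size = axial_size)
  for (arm in c("uct_guided", "degraded")) {
    pairs_ts <- make_pairs(cohort[train_ids], "TS", arm,
                           axial_size = axial_size,
                           dilate_voxels = dilate_voxels)
    pairs_rcs <- make_pairs(cohort[train_ids], "RCS", arm,
                            axial_size = axial_size,
                            dilate_voxels = dilate_voxels)
    cfg_ts <- config; cfg_ts$stage <- "TS"
    cfg_rcs <- config; cfg_rcs$stage <- "RCS"
    ts <- train_stage(pairs_ts, list(), net_config, cfg_ts)
    rcs <- train_stage(pairs_rcs, list(), net_config, cfg_rcs)
    reports <- evaluate_cascade(ts$model, rcs$model, test_ts, test_rcs)
    arms[[arm]] <- reports
  }
  flatten <- function(reports)
    unlist(lapply(reports, function(r) list(r$tooth, r$canal)),
           recursive = FALSE)
  agg <- function(reports) {
    fl <- flatten(reports)
    c(dsc = mean(vapply(fl, `[[`, numeric(1), "dsc")),
      sen = mean(vapply(fl, `[[`, numeric(1), "sen")),
      iou = mean(vapply(fl, `[[`, numeric(1), "iou")))
  }
  list(uct = agg(arms$uct_guided), degraded = agg(arms$degraded),
       reports = arms,
       table = compare_arms(flatten(arms$uct_guided),
                            flatten(arms$degraded)))
}

#' Voxel-size resampling experiment
#'
#' For each target voxel size: resample the cohort's CBCT volumes, transfer
#' the micro-CT labels onto each resampled grid through the already
#' estimated per-tooth transform (the ground truth is regenerated per
#' grid, so it varies with voxel size by construction), train a cascade,
#' and evaluate Dice/sensitivity/IoU on the held-out phantoms.
#'
#' @param cohort labelled cohort from [transfer_cohort_labels()].
#' @param targets target voxel sizes in mm.
#' @param n_test held-out phantoms (cohort tail).
#' @param net_config,config network and training settings.
#' @param axial_size in-plane crop size at the native voxel; scaled per
#'   target to preserve the physical window, rounded to the network's
#'   downsampling multiple.
#' @return A data frame with one row per (target, stage, metric):
#'   `target_voxel`, `stage`, `metric`, `value`.
#' @export
run_resampling_experiment <- function(cohort, targets, n_test = 1L,
                                      net_config = net_config(),
                                      config = train_config(),
                                      axial_size = 48L) {
  native <- cohort[[1]]$cbct$voxel_size[1]
  n <- length(cohort)
  train_ids <- seq_len(n - n_test)
  test_ids <- (n - n_test + 1L):n
  rows <- list()
  for (tv in targets) {
    ch <- lapply(cohort, function(pair) {
      if (abs(tv - native) > 1e-9) {
        pair$cbct <- resample_volume(pair$cbct, tv, "linear")
        masks <- threshold_uct(
          pair$uct, "global",
          value = (pair$spec$intensities$canal +
                     pair$spec$intensities$dentin) / 2)
        pair$tooth_label <- transfer_labels(masks$tooth, pair$transform,
                                            pair$cbct)
        pair$canal_label <- transfer_labels(masks$canal, pair$transform,
                                            pair$cbct)
      }
      pair
    })
    ax <- as.integer(ceiling(axial_size * native / tv /
                               net_config$pad_multiple - 1e-9) *
                       net_config$pad_multiple)
    pairs_ts <- make_pairs(ch[train_ids], "TS", axial_size = ax)
    pairs_rcs <- make_pairs(ch[train_ids], "RCS", axial_size = ax)
    test_ts <- make_pairs(ch[test_ids], "TS", axial_size = ax)
    test_rcs <- make_pairs(ch[test_ids], "RCS", axial_size = ax)
    cfg_ts <- config; cfg_ts$stage <- "TS"
    cfg_rcs <- config; cfg_rcs$stage <- "RCS"
    ts <- train_stage(pairs_ts, list(), net_config, cfg_ts)
    rcs <- train_stage(pairs_rcs, list(), net_config, cfg_rcs)
    reports <- evaluate_cascade(ts$model, rcs$model, test_ts, test_rcs)
    for (stage in c("TS", "RCS")) {
      sel <- if (stage == "TS") "tooth" else "canal"
      for (metric in c("dsc", "sen", "iou")) {
        vals <- vapply(reports, function(r) r[[sel]][[metric]], numeric(1))
        rows[[length(rows) + 1]] <- data.frame(
          target_voxel = tv, stage = stage, metric = metric,
          value = mean(vals))
      }
    }
  }
  do.call(rbind, rows)
}
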