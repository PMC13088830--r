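#' Configuration of the nested-U segmentation network
#'
#' The network is a two-level U structure: an outer encoder-decoder whose
#' every stage is itself a small residual U-block (RSU), with side outputs
#' from each decoder stage and the bottom fused into the final probability
#' map (deep supervision). The `"tiny"` variant (under one million
#' parameters) is the configuration used throughout the desk-scale
#' experiments and tests; the `"full"` variant is a full-size
#' nested-U channel schedule sharing the identical interface.
#'
#' @param variant `"tiny"` or `"full"`, or `"custom"` with explicit
#'   `stages`/`bottom`.
#' @param stages list of outer encoder stages, each
#'   `list(depth =, mid =, out =)` (inner-U depth, mid channels, output
#'   channels); mirrored by the decoder. At least 2 stages.
#' @param bottom the bottom stage, same form.
#' @param in_channels,out_channels fixed at 1 for grayscale in, one
#'   foreground probability out.
#' @return An object of class `net_config`.
#' @export
net_config <- function(variant = c("tiny", "full", "custom"),
                       stages = NULL, bottom = NULL,
                       in_channels = 1L, out_channels = 1L) {
  variant <- match.arg(variant)
  if (variant == "tiny") {
    stages <- list(list(depth = 3L, mid = 6L, out = 12L),
                   list(depth = 3L, mid = 6L, out = 12L))
    bottom <- list(depth = 2L, mid = 6L, out = 12L)
  } else if (variant == "full") {
    stages <- list(list(depth = 7L, mid = 32L, out = 64L),
                   list(depth = 6L, mid = 32L, out = 128L),
                   list(depth = 5L, mid = 64L, out = 256L),
                   list(depth = 4L, mid = 128L, out = 512L))
    bottom <- list(depth = 4L, mid = 256L, out = 512L)
  }
  if (is.null(stages) || is.null(bottom))
    stop("custom variant requires explicit `stages` and `bottom`")
  if (length(stages) < 2L)
    stop("at least 2 encoder stages required (3 stages incl. bottom)")
  for (st in c(stages, list(bottom)))
    if (st$depth < 2L || st$mid < 1L || st$out < 1L)
      stop("invalid stage: depth >= 2 and positive channel counts required")
  cfg <- structure(list(variant = variant, in_channels = as.integer(in_channels),
                        out_channels = as.integer(out_channels),
                        stages = stages, bottom = bottom,
                        side_supervision = TRUE),
                   class = "net_config")
  # total downsampling: outer pools + deepest inner-U pools
  outer_pools <- length(stages)
  inner_pools <- max(vapply(c(stages, list(bottom)),
                            function(s) s$depth - 1L, integer(1)))
  cfg$pad_multiple <- as.integer(2^(outer_pools + inner_pools))
  cfg
}

#' Build a segmentation model with seeded weights
#'
#' Weights use He-normal initialization; the same seed reproduces the same
#' initial weights bit for bit.
#'
#' @param config a [net_config()].
#' @param seed integer seed.
#' @return An object of class `seg_model` holding `params` and `config`.
#' @export
build_model <- function(config, seed = 1L) {
  stopifnot(inherits(config, "net_config"))
  set.seed(seed)
  structure(list(params = net_init(config), config = config),
            class = "seg_model")
}

#' @export
print.seg_model <- function(x, ...) {
  cat(sprintf("<seg_model> %s variant, %d stages + bottom, %d parameters\n",
              x$config$variant, length(x$config$stages),
              model_parameter_count(x)))
  invisible(x)
}

#' Total trainable parameter count of a model
#' @param model a [seg_model][build_model()].
#' @return Integer parameter count.
#' @export
model_parameter_count <- function(model) param_count(model$params)

# pad a slice (H, W, 1) to multiples of `m` with `fill`, returning the
# padded cube and the original dims
pad_slice <- function(x, m, fill) {
  d <- dim(x)
  H <- as.integer(ceiling(d[1] / m) * m)
  W <- as.integer(ceiling(d[2] / m) * m)
  if (H == d[1] && W == d[2]) return(list(x = x, orig = d[1:2]))
  out <- array(fill, c(H, W, d[3]))
  out[seq_len(d[1]), seq_len(d[2]), ] <- x
  list(x = out, orig = d[1:2])
}

#' Slice-wise inference over a volume
#'
#' Intensities are min-max normalized to \[0, 1\] over the whole volume,
#' each axial slice is passed through the network independently (padded
#' internally to the network's downsampling multiple and cropped back), and
#' the fused sigmoid output is assembled into a probability volume on the
#' input grid.
#'
#' @param model a trained [seg_model][build_model()].
#' @param vol a [volume3d()].
#' @param batch kept for interface stability; slices are processed
#'   sequentially.
#' @return A [volume3d()] of probabilities in \[0, 1\].
#' @export
predict_volume <- function(model, vol, batch = 8L) {
  stopifnot(inherits(model, "seg_model"), inherits(vol, "volume3d"))
  arr <- normalize_minmax(vol$data)
  d <- dim(arr)
  out <- array(0, d)
  for (k in seq_len(d[3])) {
    sl <- array(arr[, , k], c(d[1], d[2], 1L))
    pd <- pad_slice(sl, model$config$pad_multiple, 0)
    fw <- net_fwd(model$params, model$config, pd$x)
    prob <- sigmoid(fw$fused[, , 1])
    out[, , k] <- prob[seq_len(d[1]), seq_len(d[2])]
  }
  volume3d(out, vol$voxel_size, vol$origin)
}

normalize_minmax <- function(arr) {
  r <- range(arr)
  if (diff(r) == 0) return(arr * 0)
  (arr - r[1]) / diff(r)
}

#' Save a model checkpoint
#'
#' Writes the serialized weights to `path` and a human-readable JSON config
#' sidecar to `paste0(path, ".json")`.
#'
#' @param model a [seg_model][build_model()].
#' @param path checkpoint file path (conventionally `.ckpt`).
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "seg_model"))
  saveRDS(model, path)
  cfg <- model$config
  jsonlite::write_json(
    list(variant = cfg$variant, stages = cfg$stages, bottom = cfg$bottom,
         in_channels = cfg$in_channels, out_channels = cfg$out_channels,
         n_parameters = model_parameter_count(model)),
    paste0(path, ".json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Load a model checkpoint
#' @param path checkpoint file written by [save_checkpoint()].
#' @return The [seg_model][build_model()].
#' @export
load_checkpoint <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "seg_model"))
  model
}
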