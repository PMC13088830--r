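# Internal neural-network machinery for the nested-U segmentation model.
# Feature maps are (H, W, C) arrays; 3x3 conv weights are (9*Cin) x Cout
# matrices feeding the im2col GEMM kernels in src/ops.cpp. Backward passes
# are hand-derived and mirror the forward caches.

conv_init <- function(c_in, c_out, k = 3L) {
  fan_in <- k * k * c_in
  list(W = matrix(rnorm(k * k * c_in * c_out, sd = sqrt(2 / fan_in)),
                  k * k * c_in, c_out),
       b = numeric(c_out))
}

conv1x1_init <- function(c_in, c_out = 1L) {
  list(w = matrix(rnorm(c_in * c_out, sd = sqrt(2 / c_in)), c_in, c_out),
       b = numeric(c_out))
}

# 3x3 conv + ReLU; the im2col matrix lives on the C++ heap (external
# pointer) between the forward and backward passes
cr_fwd <- function(p, x) {
  r <- cpp_conv2d_fwd(x, p$W, p$b)
  list(a = r$a, M = r$M, c_in = dim(x)[3])
}

cr_bwd <- function(p, cache, da) {
  r <- cpp_conv2d_bwd(cache$M, p$W, da, cache$a, cache$c_in)
  list(dx = r$dx, g = list(W = r$dW, b = as.numeric(r$db)))
}

conv1x1_fwd <- function(p, x) {
  d <- dim(x)
  y <- matrix(x, ncol = d[3]) %*% p$w + p$b
  array(y, c(d[1], d[2], ncol(p$w)))
}

conv1x1_bwd <- function(p, x, dy) {
  d <- dim(x)
  dym <- matrix(dy, ncol = ncol(p$w))
  xm <- matrix(x, ncol = d[3])
  list(dx = array(dym %*% t(p$w), d),
       g = list(w = crossprod(xm, dym), b = colSums(dym)))
}

cube_cat <- function(a, b) {
  da <- dim(a); db <- dim(b)
  array(c(a, b), c(da[1], da[2], da[3] + db[3]))
}

# ---- residual U-block (RSU): a small U-net inside one stage -------------

rsu_init <- function(depth, c_in, c_mid, c_out) {
  stopifnot(depth >= 2L)
  enc <- vector("list", depth)
  enc[[1]] <- conv_init(c_out, c_mid)
  for (j in 2:depth) enc[[j]] <- conv_init(c_mid, c_mid)
  dec <- vector("list", depth)
  for (j in depth:2) dec[[j]] <- conv_init(2 * c_mid, c_mid)
  dec[[1]] <- conv_init(2 * c_mid, c_out)
  list(conv_in = conv_init(c_in, c_out), enc = enc, bottom = conv_init(c_mid, c_mid),
       dec = dec)
}

rsu_fwd <- function(p, x) {
  L <- length(p$enc)
  xin <- cr_fwd(p$conv_in, x)
  e <- vector("list", L)
  pools <- vector("list", L)
  e[[1]] <- cr_fwd(p$enc[[1]], xin$a)
  for (j in 2:L) {
    pl <- cpp_maxpool2_fwd(e[[j - 1]]$a)
    pools[[j]] <- list(argmax = pl$argmax, in_dim = dim(e[[j - 1]]$a))
    e[[j]] <- cr_fwd(p$enc[[j]], pl$y)
  }
  b <- cr_fwd(p$bottom, e[[L]]$a)
  dcur <- b$a
  dcv <- vector("list", L)
  up_dims <- vector("list", L)
  for (j in L:1) {
    if (j == L) {
      upx <- dcur
    } else {
      dl <- dim(e[[j]]$a)
      up_dims[[j]] <- dim(dcur)
      upx <- cpp_upsample2_fwd(dcur, dl[1], dl[2])
    }
    n_up <- dim(upx)[3]
    cc <- cube_cat(upx, e[[j]]$a)
    dcv[[j]] <- cr_fwd(p$dec[[j]], cc)
    dcv[[j]]$n_up <- n_up
    dcur <- dcv[[j]]$a
  }
  list(a = xin$a + dcur,
       cache = list(xin = xin, e = e, pools = pools, b = b, dcv = dcv,
                    up_dims = up_dims))
}

rsu_bwd <- function(p, cache, dout) {
  L <- length(p$enc)
  g <- list(conv_in = NULL, enc = vector("list", L), bottom = NULL,
            dec = vector("list", L))
  de <- vector("list", L)
  dcur <- dout
  for (j in 1:L) {
    r <- cr_bwd(p$dec[[j]], cache$dcv[[j]], dcur)
    g$dec[[j]] <- r$g
    n_up <- cache$dcv[[j]]$n_up
    dcc <- r$dx
    dup <- dcc[, , seq_len(n_up), drop = FALSE]
    dskip <- dcc[, , (n_up + 1):dim(dcc)[3], drop = FALSE]
    de[[j]] <- if (is.null(de[[j]])) dskip else de[[j]] + dskip
    dcur <- if (j == L) dup
            else cpp_upsample2_bwd(dup, cache$up_dims[[j]][1],
                                   cache$up_dims[[j]][2])
  }
  rb <- cr_bwd(p$bottom, cache$b, dcur)
  g$bottom <- rb$g
  de[[L]] <- de[[L]] + rb$dx
  dxin <- dout                           # residual branch
  for (j in L:1) {
    r <- cr_bwd(p$enc[[j]], cache$e[[j]], de[[j]])
    g$enc[[j]] <- r$g
    if (j > 1) {
      dprev <- cpp_maxpool2_bwd(r$dx, cache$pools[[j]]$argmax,
                                cache$pools[[j]]$in_dim[1],
                                cache$pools[[j]]$in_dim[2])
      de[[j - 1]] <- de[[j - 1]] + dprev
    } else {
      dxin <- dxin + r$dx
    }
  }
  r <- cr_bwd(p$conv_in, cache$xin, dxin)
  g$conv_in <- r$g
  list(dx = r$dx, g = g)
}

# ---- full nested-U network ----------------------------------------------

net_init <- function(cfg) {
  S <- length(cfg$stages)
  enc <- vector("list", S)
  dec <- vector("list", S)
  c_prev <- cfg$in_channels
  for (s in seq_len(S)) {
    st <- cfg$stages[[s]]
    enc[[s]] <- rsu_init(st$depth, c_prev, st$mid, st$out)
    c_prev <- st$out
  }
  bt <- cfg$bottom
  bottom <- rsu_init(bt$depth, c_prev, bt$mid, bt$out)
  up_ch <- bt$out
  for (s in S:1) {
    st <- cfg$stages[[s]]
    dec[[s]] <- rsu_init(st$depth, up_ch + st$out, st$mid, st$out)
    up_ch <- st$out
  }
  side <- c(lapply(seq_len(S), function(s) conv1x1_init(cfg$stages[[s]]$out)),
            list(conv1x1_init(bt$out)))
  list(enc = enc, bottom = bottom, dec = dec, side = side,
       fuse = conv1x1_init(S + 1L))
}

# Upsample a 1-channel logit map from pyramid level `lev` to level 1,
# caching intermediate dims for the backward chain. dims_list[[l]] is the
# (H, W) of level l.
side_up_fwd <- function(x, lev, dims_list) {
  steps <- list()
  cur <- x
  if (lev > 1) for (l in (lev - 1):1) {
    steps[[length(steps) + 1]] <- dim(cur)
    cur <- cpp_upsample2_fwd(cur, dims_list[[l]][1], dims_list[[l]][2])
  }
  list(a = cur, steps = steps)
}

side_up_bwd <- function(dy, steps) {
  cur <- dy
  for (sd in rev(steps)) cur <- cpp_upsample2_bwd(cur, sd[1], sd[2])
  cur
}

net_fwd <- function(params, cfg, x) {
  S <- length(cfg$stages)
  f <- vector("list", S)
  pools <- vector("list", S)
  dims_list <- vector("list", S + 1L)
  cur <- x
  for (s in seq_len(S)) {
    dims_list[[s]] <- dim(cur)[1:2]
    f[[s]] <- rsu_fwd(params$enc[[s]], cur)
    pl <- cpp_maxpool2_fwd(f[[s]]$a)
    pools[[s]] <- list(argmax = pl$argmax, in_dim = dim(f[[s]]$a))
    cur <- pl$y
  }
  dims_list[[S + 1L]] <- dim(cur)[1:2]
  fb <- rsu_fwd(params$bottom, cur)
  d <- vector("list", S)
  up_dims <- vector("list", S)
  dcur <- fb$a
  for (s in S:1) {
    dl <- dim(f[[s]]$a)
    up_dims[[s]] <- dim(dcur)
    upx <- cpp_upsample2_fwd(dcur, dl[1], dl[2])
    cc <- cube_cat(upx, f[[s]]$a)
    d[[s]] <- rsu_fwd(params$dec[[s]], cc)
    d[[s]]$n_up <- dim(upx)[3]
    dcur <- d[[s]]$a
  }
  n_side <- S + 1L
  side_logits <- vector("list", n_side)
  side_small <- vector("list", n_side)
  side_steps <- vector("list", n_side)
  for (s in seq_len(S)) {
    sl <- conv1x1_fwd(params$side[[s]], d[[s]]$a)
    up <- side_up_fwd(sl, s, dims_list)
    side_small[[s]] <- sl
    side_logits[[s]] <- up$a
    side_steps[[s]] <- up$steps
  }
  sl <- conv1x1_fwd(params$side[[n_side]], fb$a)
  up <- side_up_fwd(sl, S + 1L, dims_list)
  side_small[[n_side]] <- sl
  side_logits[[n_side]] <- up$a
  side_steps[[n_side]] <- up$steps
  cat_sides <- Reduce(cube_cat, side_logits)
  fused <- conv1x1_fwd(params$fuse, cat_sides)
  list(fused = fused, sides = side_logits,
       cache = list(f = f, pools = pools, fb = fb, d = d, up_dims = up_dims,
                    side_small = side_small, side_steps = side_steps,
                    cat_sides = cat_sides, dims_list = dims_list))
}

# dlogits: list(fused = ..., sides = list of full-resolution gradients)
net_bwd <- function(params, cfg, cache, dlogits) {
  S <- length(cfg$stages)
  n_side <- S + 1L
  g <- list(enc = vector("list", S), bottom = NULL,
            dec = vector("list", S), side = vector("list", n_side),
            fuse = NULL)
  fz <- conv1x1_bwd(params$fuse, cache$cat_sides, dlogits$fused)
  g$fuse <- fz$g
  dd <- vector("list", S)     # grads wrt decoder-stage outputs
  dfb <- NULL
  for (i in seq_len(n_side)) {
    dside_full <- fz$dx[, , i, drop = FALSE] + dlogits$sides[[i]]
    dsmall <- side_up_bwd(dside_full, cache$side_steps[[i]])
    src <- if (i <= S) cache$d[[i]]$a else cache$fb$a
    sb <- conv1x1_bwd(params$side[[i]], src, dsmall)
    g$side[[i]] <- sb$g
    if (i <= S) dd[[i]] <- sb$dx else dfb <- sb$dx
  }
  df <- vector("list", S)     # grads wrt encoder-stage outputs
  dcur <- dd[[1]]
  for (s in seq_len(S)) {
    if (s > 1) dcur <- dcur + dd[[s]]
    r <- rsu_bwd(params$dec[[s]], cache$d[[s]]$cache, dcur)
    g$dec[[s]] <- r$g
    n_up <- cache$d[[s]]$n_up
    dup <- r$dx[, , seq_len(n_up), drop = FALSE]
    dskip <- r$dx[, , (n_up + 1):dim(r$dx)[3], drop = FALSE]
    df[[s]] <- dskip
    dcur <- cpp_upsample2_bwd(dup, cache$up_dims[[s]][1],
                              cache$up_dims[[s]][2])
  }
  dfb <- dfb + dcur
  r <- rsu_bwd(params$bottom, cache$fb$cache, dfb)
  g$bottom <- r$g
  dpool <- r$dx
  for (s in S:1) {
    dfs <- df[[s]] + cpp_maxpool2_bwd(dpool, cache$pools[[s]]$argmax,
                                      cache$pools[[s]]$in_dim[1],
                                      cache$pools[[s]]$in_dim[2])
    r <- rsu_bwd(params$enc[[s]], cache$f[[s]]$cache, dfs)
    g$enc[[s]] <- r$g
    dpool <- r$dx
  }
  g
}

# ---- parameter-tree utilities and Adam ----------------------------------

is_leaf_param <- function(x) is.numeric(x) || is.matrix(x)

param_map2 <- function(f, a, b) {
  if (is_leaf_param(a)) return(f(a, b))
  out <- a
  for (nm in seq_along(a)) out[[nm]] <- param_map2(f, a[[nm]], b[[nm]])
  out
}

param_map <- function(f, a) {
  if (is_leaf_param(a)) return(f(a))
  out <- a
  for (nm in seq_along(a)) out[[nm]] <- param_map(f, a[[nm]])
  out
}

param_count <- function(params) {
  total <- 0
  walk <- function(x) {
    if (is_leaf_param(x)) total <<- total + length(x)
    else for (e in x) walk(e)
  }
  walk(params)
  total
}

adam_init <- function(params) {
  list(m = param_map(function(x) x * 0, params),
       v = param_map(function(x) x * 0, params),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- param_map2(function(m, g) beta1 * m + (1 - beta1) * g,
                        state$m, grads)
  state$v <- param_map2(function(v, g) beta2 * v + (1 - beta2) * g^2,
                        state$v, grads)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- param_map2(function(m, v) lr * (m / bc1) / (sqrt(v / bc2) + eps),
                    state$m, state$v)
  params <- param_map2(`-`, params, upd)
  list(params = params, state = state)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

softplus <- function(x) pmax(x, 0) + log1p(exp(-abs(x)))

# Deep-supervised loss on one slice: mean over all outputs (fused + sides)
# of binary cross-entropy plus an optional soft-Dice addend. Returns the
# loss value and the gradient wrt each logit map.
slice_loss <- function(fwd, y, dice_weight = 0) {
  outs <- c(list(fwd$fused), fwd$sides)
  n_out <- length(outs)
  npix <- length(y)
  total <- 0
  dlog <- vector("list", n_out)
  ya <- array(as.numeric(y), c(dim(y), 1L))
  for (i in seq_len(n_out)) {
    l <- outs[[i]]
    p <- sigmoid(l)
    bce <- mean(softplus(l) - ya * l)
    loss_i <- bce
    dl <- (p - ya) / npix
    if (dice_weight > 0) {
      eps <- 1
      num <- 2 * sum(p * ya) + eps
      den <- sum(p) + sum(ya) + eps
      loss_i <- loss_i + dice_weight * (1 - num / den)
      ds_dp <- (2 * ya * den - num) / den^2
      dl <- dl - dice_weight * ds_dp * p * (1 - p)
    }
    total <- total + loss_i / n_out
    dlog[[i]] <- dl / n_out
  }
  list(loss = total, dlogits = list(fused = dlog[[1]], sides = dlog[-1]))
}
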