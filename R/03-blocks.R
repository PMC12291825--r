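# Backbone building blocks.
#
# All blocks consume and produce (H, W, C, N) feature maps. Backward
# passes mirror the forward graphs by hand; the full-network
# finite-difference checks in the test suite guard the algebra.

# ---- stem --------------------------------------------------------------

#' Stem module
#'
#' Entry block of the backbone: a 7x7 convolution with stride 2 (followed
#' by batch normalization and ReLU), then 3x3 max pooling with stride 2.
#' Each stage halves the spatial side, so a 224x224x3 image becomes a
#' 56x56 map with `stem_channels` channels.
#'
#' @param cfg a [wormnet_config()].
#' @return a module; run it with [wn_forward()]. Inputs must have exactly 3
#'   channels.
#' @export
stem_module <- function(cfg = wormnet_config()) {
  new_module("wn_stem",
    children = list(
      conv = conv2d_layer(3, cfg$stem_channels, 7, stride = 2),
      bn = bn_layer(cfg$stem_channels),
      relu = relu_layer(),
      pool = maxpool_layer(3, 2, 1)
    ))
}

#' @export
wn_forward.wn_stem <- function(m, x, training = FALSE) {
  if (length(dim(x)) != 4 || dim(x)[3] != 3) {
    stop(sprintf("stem expects a (H, W, 3, N) image array, got channels = %s",
                 if (length(dim(x)) == 4) dim(x)[3] else "?"))
  }
  if (min(dim(x)[1:2]) < 32) stop("stem input spatial size must be >= 32")
  for (ch in m$children) x <- wn_forward(ch, x, training)
  x
}

#' @export
wn_backward.wn_stem <- function(m, dy) {
  for (ch in rev(m$children)) dy <- wn_backward(ch, dy)
  dy
}

# ---- feature mask module (spatial purification) ------------------------

#' Feature mask module (FMM)
#'
#' Spatial attention that purifies a feature map: per-pixel average and
#' maximum over channels give two one-channel maps, whose concatenation is
#' passed through a 7x7 convolution and a sigmoid to produce a
#' single-channel mask with values strictly inside (0, 1). The output is
#' the input multiplied by the mask, broadcast over channels, so shape is
#' preserved and no output element exceeds its input in magnitude.
#'
#' @param kernel spatial kernel of the mask convolution (default 7).
#' @return a module.
#' @export
fmm_module <- function(kernel = 7) {
  new_module("wn_fmm",
    children = list(conv = conv2d_layer(2, 1, kernel)))
}

# channel-wise reduce helpers: rows of the reshaped matrix run over
# (h, w, n), columns over channels
.chan_matrix <- function(x) {
  d <- dim(x)
  matrix(aperm(x, c(1, 2, 4, 3)), ncol = d[3])
}

.chan_unmatrix <- function(v, d) {
  # v ordered over (h, w, n) -> (H, W, 1, N)
  array(v, c(d[1], d[2], 1, d[4]))
}

#' @export
wn_forward.wn_fmm <- function(m, x, training = FALSE) {
  d <- dim(x)
  xm <- .chan_matrix(x)
  avg <- rowMeans(xm)
  amax <- max.col(xm, ties.method = "first")
  mx <- xm[cbind(seq_len(nrow(xm)), amax)]
  s <- array(0, c(d[1], d[2], 2, d[4]))
  s[, , 1, ] <- array(avg, c(d[1], d[2], d[4]))
  s[, , 2, ] <- array(mx, c(d[1], d[2], d[4]))
  pre <- wn_forward(m$children$conv, s, training)
  mask <- sigmoid(pre)
  y <- x * as.vector(mask[, , rep(1, d[3]), , drop = FALSE])
  dim(y) <- d
  if (training) {
    m$cache_x <- x
    m$cache_mask <- mask
    m$cache_amax <- amax
  }
  y
}

#' @export
wn_backward.wn_fmm <- function(m, dy) {
  x <- m$cache_x
  mask <- m$cache_mask
  d <- dim(x)
  dx <- dy * as.vector(mask[, , rep(1, d[3]), , drop = FALSE])
  dim(dx) <- d
  # gradient into the mask, summed over channels
  dmask <- .chan_unmatrix(rowSums(.chan_matrix(dy * x)), d)
  dpre <- dmask * mask * (1 - mask)
  ds <- wn_backward(m$children$conv, dpre)
  # average path: spread equally over channels
  davg <- ds[, , 1, , drop = FALSE] / d[3]
  dx2 <- array(as.vector(davg[, , rep(1, d[3]), , drop = FALSE]), d)
  # max path: route to the argmax channel of each pixel
  dmax <- as.vector(ds[, , 2, , drop = FALSE])
  sm <- matrix(0, d[1] * d[2] * d[4], d[3])
  sm[cbind(seq_len(nrow(sm)), m$cache_amax)] <- dmax
  dx3 <- aperm(array(sm, c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
  m$cache_x <- NULL
  m$cache_mask <- NULL
  m$cache_amax <- NULL
  dx + dx2 + dx3
}

# ---- channel interaction module ---------------------------------------

#' Channel interaction module (CIM)
#'
#' Dual-branch channel recalibration. With both branches enabled, two 1x1
#' convolutions aggregate the C input channels into two C/2-channel
#' sub-features. The local branch condenses its sub-feature by global
#' average pooling, learns channel dependencies with a 1-D convolution
#' whose kernel size follows [eca_kernel_size()], applies a sigmoid, and
#' rescales its sub-feature by the resulting weights. The global branch
#' represents each channel by its L2 norm and rescales by the normalized
#' norms (they sum to one per sample, up to the epsilon guarding an
#' all-zero input). The two recalibrated sub-features are concatenated and
#' fused by a 1x1 convolution (with batch normalization, no ReLU) back to C
#' channels. No residual connection is applied inside the module; the
#' surrounding multi-order block owns the residual.
#'
#' With only one of `use_local`/`use_global` the corresponding single
#' branch is applied directly to all C channels (channel attention alone,
#' or divisive normalization alone), which is exactly how the module
#' decomposes in ablation studies.
#'
#' @param channels input/output channel count C (divisible by 2 when both
#'   branches are active).
#' @param use_local,use_global branch switches.
#' @return a module (the identity module when both switches are off).
#' @export
cim_module <- function(channels, use_local = TRUE, use_global = TRUE) {
  if (!use_local && !use_global) return(identity_module())
  if (use_local && use_global) {
    if (channels %% 2 != 0) stop("cim: channels must be divisible by 2")
    half <- channels %/% 2
    new_module("wn_cim",
      channels = channels, half = half, mode = "both", eps = 1e-6,
      children = list(
        agg_l = cbr_module(channels, half, 1),
        agg_g = cbr_module(channels, half, 1),
        conv1d = conv1d_layer(eca_kernel_size(half)),
        fuse_conv = conv2d_layer(channels, channels, 1),
        fuse_bn = bn_layer(channels)
      ))
  } else if (use_local) {
    new_module("wn_cim",
      channels = channels, half = channels, mode = "local", eps = 1e-6,
      children = list(conv1d = conv1d_layer(eca_kernel_size(channels))))
  } else {
    new_module("wn_cim", channels = channels, half = channels,
               mode = "global", eps = 1e-6, children = list())
  }
}

# per-(channel, sample) reduce: colSums of matrix(x, nrow = H*W) gives a
# (C, N) matrix
.cn_sums <- function(x) {
  d <- dim(x)
  matrix(.colSums(x, d[1] * d[2], d[3] * d[4]), d[3], d[4])
}

cim_local_fwd <- function(m, x1, training) {
  d <- dim(x1)
  hw <- d[1] * d[2]
  xl <- .cn_sums(x1) / hw                                   # GAP -> (C, N)
  wl <- sigmoid(wn_forward(m$children$conv1d, xl, training))
  yl <- x1 * bcast_cn(wl, hw)
  dim(yl) <- d
  if (training) {
    m$cache_x1 <- x1
    m$cache_wl <- wl
  }
  yl
}

cim_local_bwd <- function(m, dyl) {
  x1 <- m$cache_x1
  wl <- m$cache_wl
  d <- dim(x1)
  hw <- d[1] * d[2]
  dwl <- .cn_sums(dyl * x1)
  dx <- dyl * bcast_cn(wl, hw)
  dim(dx) <- d
  dpre <- dwl * wl * (1 - wl)
  dxl <- wn_backward(m$children$conv1d, dpre)
  dx <- dx + bcast_cn(dxl / hw, hw)
  dim(dx) <- d
  m$cache_x1 <- NULL
  m$cache_wl <- NULL
  dx
}

cim_global_fwd <- function(m, x2, training) {
  d <- dim(x2)
  hw <- d[1] * d[2]
  nrm <- sqrt(.cn_sums(x2 * x2))                            # (C, N) L2 norms
  wg <- sweep(nrm, 2, colSums(nrm) + m$eps, "/")
  yg <- x2 * bcast_cn(wg, hw)
  dim(yg) <- d
  if (training) {
    m$cache_x2 <- x2
    m$cache_nrm <- nrm
    m$cache_wg <- wg
  }
  yg
}

cim_global_bwd <- function(m, dyg) {
  x2 <- m$cache_x2
  nrm <- m$cache_nrm
  wg <- m$cache_wg
  d <- dim(x2)
  hw <- d[1] * d[2]
  dwg <- .cn_sums(dyg * x2)
  dx <- dyg * bcast_cn(wg, hw)
  dim(dx) <- d
  s <- colSums(nrm) + m$eps
  # d wg_c / d nrm_k = delta_ck / S - nrm_c / S^2, summed against dwg
  dnrm <- sweep(dwg, 2, s, "/") -
    matrix(rep(colSums(dwg * nrm) / s^2, each = nrow(nrm)), nrow(nrm))
  # d||v||/dv = v / ||v|| (guard zero norms)
  dx <- dx + x2 * bcast_cn(dnrm / pmax(nrm, 1e-12), hw)
  dim(dx) <- d
  m$cache_x2 <- NULL
  m$cache_nrm <- NULL
  m$cache_wg <- NULL
  dx
}

#' @export
wn_forward.wn_cim <- function(m, x, training = FALSE) {
  if (m$mode == "local") return(cim_local_fwd(m, x, training))
  if (m$mode == "global") return(cim_global_fwd(m, x, training))
  x1 <- wn_forward(m$children$agg_l, x, training)
  x2 <- wn_forward(m$children$agg_g, x, training)
  yl <- cim_local_fwd(m, x1, training)
  yg <- cim_global_fwd(m, x2, training)
  d <- dim(x)
  cat2 <- array(0, c(d[1], d[2], m$channels, d[4]))
  cat2[, , seq_len(m$half), ] <- yl
  cat2[, , m$half + seq_len(m$half), ] <- yg
  y <- wn_forward(m$children$fuse_conv, cat2, training)
  wn_forward(m$children$fuse_bn, y, training)
}

#' @export
wn_backward.wn_cim <- function(m, dy) {
  if (m$mode == "local") return(cim_local_bwd(m, dy))
  if (m$mode == "global") return(cim_global_bwd(m, dy))
  dy <- wn_backward(m$children$fuse_bn, dy)
  dcat <- wn_backward(m$children$fuse_conv, dy)
  dyl <- dcat[, , seq_len(m$half), , drop = FALSE]
  dyg <- dcat[, , m$half + seq_len(m$half), , drop = FALSE]
  dx1 <- cim_local_bwd(m, dyl)
  dx2 <- cim_global_bwd(m, dyg)
  wn_backward(m$children$agg_l, dx1) + wn_backward(m$children$agg_g, dx2)
}

#' Channel weights computed by the interaction branches
#'
#' Convenience accessor used in analyses and tests: runs the module on a
#' feature map and returns the channel weight vectors of the branches from
#' the most recent forward pass.
#'
#' @param m a `wn_cim` module built by [cim_module()].
#' @param x a feature map.
#' @return list with elements `wl` (local sigmoid weights, `(C', N)`) and/or
#'   `wg` (global normalized weights, columns summing to one), depending on
#'   the module's mode.
#' @export
cim_channel_weights <- function(m, x) {
  stopifnot(inherits(m, "wn_cim"))
  wl <- NULL
  wg <- NULL
  if (m$mode %in% c("both", "local")) {
    x1 <- if (m$mode == "both") wn_forward(m$children$agg_l, x) else x
    d <- dim(x1)
    xl <- .cn_sums(x1) / (d[1] * d[2])
    wl <- sigmoid(wn_forward(m$children$conv1d, xl))
  }
  if (m$mode %in% c("both", "global")) {
    x2 <- if (m$mode == "both") wn_forward(m$children$agg_g, x) else x
    nrm <- sqrt(.cn_sums(x2 * x2))
    wg <- sweep(nrm, 2, colSums(nrm) + m$eps, "/")
  }
  list(wl = wl, wg = wg)
}

# ---- multi-order block -------------------------------------------------

#' Multi-order extraction block
#'
#' The backbone's residual unit. Two parallel 1x1 convolutions (each with
#' batch normalization and ReLU) aggregate the input into two sub-features
#' of a quarter of the output width. One sub-feature is kept as an identity
#' branch; the other passes through three parallel depth-wise convolutions
#' with kernel sizes 3x3, 5x5 and 7x7 (each with BN and ReLU), capturing
#' multiple granularities at low parameter cost. The four C/4-wide maps are
#' concatenated back to C channels, passed through the supplied interaction
#' module, and added to the block input (projected by a 1x1 convolution
#' when the shape changes).
#'
#' @param in_ch,out_ch input/output channel counts; `out_ch` must be
#'   divisible by 4.
#' @param stride spatial stride of the block (2 at downsampling stage
#'   entries, else 1); applied in the aggregation convolutions and in the
#'   identity projection.
#' @param interaction interaction module applied to the concatenated
#'   feature before the residual addition: an [fmm_module()],
#'   [cim_module()] or [identity_module()].
#' @param dw_kernels depth-wise kernel sizes (fixed 3/5/7 in the standard
#'   architecture).
#' @return a module.
#' @export
multi_order_block <- function(in_ch, out_ch, stride = 1,
                              interaction = identity_module(),
                              dw_kernels = c(3, 5, 7)) {
  if (out_ch %% 4 != 0) {
    stop(sprintf("multi-order block: out_ch = %d not divisible by 4", out_ch))
  }
  q <- out_ch %/% 4
  dws <- lapply(dw_kernels, function(k) {
    seq_module(list(dw = dwconv_layer(q, k), bn = bn_layer(q),
                    relu = relu_layer()))
  })
  names(dws) <- paste0("dw", dw_kernels)
  children <- list(
    agg1 = cbr_module(in_ch, q, 1, stride),
    agg2 = cbr_module(in_ch, q, 1, stride),
    inter = interaction
  )
  children <- c(children, dws)
  needs_proj <- (in_ch != out_ch) || (stride != 1)
  if (needs_proj) {
    children$proj_conv <- conv2d_layer(in_ch, out_ch, 1, stride)
    children$proj_bn <- bn_layer(out_ch)
  }
  new_module("wn_mo_block",
    in_ch = in_ch, out_ch = out_ch, q = q, stride = as.integer(stride),
    dw_kernels = dw_kernels, needs_proj = needs_proj, children = children)
}

#' @export
wn_forward.wn_mo_block <- function(m, x, training = FALSE) {
  x1 <- wn_forward(m$children$agg1, x, training)
  x2 <- wn_forward(m$children$agg2, x, training)
  d <- dim(x1)
  q <- m$q
  y <- array(0, c(d[1], d[2], m$out_ch, d[4]))
  # concat order: identity branch, then 7x7, 5x5, 3x3 granularities
  y[, , seq_len(q), ] <- x1
  y[, , q + seq_len(q), ] <- wn_forward(m$children$dw7, x2, training)
  y[, , 2 * q + seq_len(q), ] <- wn_forward(m$children$dw5, x2, training)
  y[, , 3 * q + seq_len(q), ] <- wn_forward(m$children$dw3, x2, training)
  z <- wn_forward(m$children$inter, y, training)
  res <- if (m$needs_proj) {
    wn_forward(m$children$proj_bn,
               wn_forward(m$children$proj_conv, x, training), training)
  } else {
    x
  }
  res + z
}

#' @export
wn_backward.wn_mo_block <- function(m, dy) {
  q <- m$q
  dz <- wn_backward(m$children$inter, dy)
  dx1 <- dz[, , seq_len(q), , drop = FALSE]
  dx2 <- wn_backward(m$children$dw7, dz[, , q + seq_len(q), , drop = FALSE]) +
    wn_backward(m$children$dw5, dz[, , 2 * q + seq_len(q), , drop = FALSE]) +
    wn_backward(m$children$dw3, dz[, , 3 * q + seq_len(q), , drop = FALSE])
  dx <- wn_backward(m$children$agg1, dx1) + wn_backward(m$children$agg2, dx2)
  if (m$needs_proj) {
    dres <- wn_backward(m$children$proj_conv,
                        wn_backward(m$children$proj_bn, dy))
    dx + dres
  } else {
    dx + dy
  }
}
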