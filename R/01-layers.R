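# Primitive differentiable layers. Feature maps are (H, W, C, N) arrays;
# vector batches are (D, N) matrices (one column per sample).

he_init <- function(dims, fan_in) {
  array(rnorm(prod(dims), sd = sqrt(2 / fan_in)), dim = dims)
}

# -- 2-D convolution (dense) --------------------------------------------

conv2d_layer <- function(in_ch, out_ch, k, stride = 1, pad = NULL, bias = TRUE) {
  if (is.null(pad)) pad <- k %/% 2
  new_module("wn_conv2d",
    k = k, stride = as.integer(stride), pad = as.integer(pad),
    in_ch = in_ch, out_ch = out_ch, use_bias = bias,
    params = list(
      W = wn_param(he_init(c(k, k, in_ch, out_ch), k * k * in_ch)),
      b = wn_param(numeric(out_ch))
    ))
}

#' @export
wn_forward.wn_conv2d <- function(m, x, training = FALSE) {
  if (dim(x)[3] != m$in_ch) {
    stop(sprintf("conv2d: expected %d input channels, got %d", m$in_ch, dim(x)[3]))
  }
  if (training) m$cache_x <- x
  cpp_conv2d_forward(x, m$params$W$value, m$params$b$value, m$stride, m$pad)
}

#' @export
wn_backward.wn_conv2d <- function(m, dy) {
  g <- cpp_conv2d_backward(m$cache_x, m$params$W$value, dy, m$stride, m$pad)
  grad_add(m$params$W, g$dw)
  grad_add(m$params$b, g$db)
  m$cache_x <- NULL
  g$dx
}

# -- depth-wise convolution ---------------------------------------------

dwconv_layer <- function(channels, k, stride = 1) {
  new_module("wn_dwconv",
    k = k, stride = as.integer(stride), pad = as.integer(k %/% 2),
    channels = channels,
    params = list(
      W = wn_param(he_init(c(k, k, channels), k * k)),
      b = wn_param(numeric(channels))
    ))
}

#' @export
wn_forward.wn_dwconv <- function(m, x, training = FALSE) {
  if (training) m$cache_x <- x
  cpp_dwconv_forward(x, m$params$W$value, m$params$b$value, m$stride, m$pad)
}

#' @export
wn_backward.wn_dwconv <- function(m, dy) {
  g <- cpp_dwconv_backward(m$cache_x, m$params$W$value, dy, m$stride, m$pad)
  grad_add(m$params$W, g$dw)
  grad_add(m$params$b, g$db)
  m$cache_x <- NULL
  g$dx
}

# -- batch normalization (per channel over H, W, N) ---------------------

bn_layer <- function(channels, momentum = 0.1, eps = 1e-5) {
  new_module("wn_bn",
    channels = channels, momentum = momentum, eps = eps,
    running_mean = numeric(channels), running_var = rep(1, channels),
    params = list(
      gamma = wn_param(rep(1, channels)),
      beta = wn_param(numeric(channels))
    ))
}

# per-channel statistic helpers: columns of matrix(x, nrow = H*W) are
# (channel, sample) pairs with channel varying fastest
channel_mean <- function(x) {
  d <- dim(x)
  rowMeans(matrix(.colMeans(x, d[1] * d[2], d[3] * d[4]), d[3], d[4]))
}

# multiply/add a per-(channel, sample) matrix into a feature map: for fixed
# (c, n) the H*W spatial values are contiguous, so rep(each = H*W) aligns
bcast_cn <- function(s, hw) rep(as.vector(s), each = hw)

#' @export
wn_forward.wn_bn <- function(m, x, training = FALSE) {
  d <- dim(x)
  hw <- d[1] * d[2]
  C <- d[3]
  N <- d[4]
  if (training) {
    mu <- channel_mean(x)
    v <- channel_mean(x * x) - mu^2
    v <- pmax(v, 0)
    m$running_mean <- (1 - m$momentum) * m$running_mean + m$momentum * mu
    m$running_var <- (1 - m$momentum) * m$running_var + m$momentum * v
  } else {
    mu <- m$running_mean
    v <- m$running_var
  }
  std <- sqrt(v + m$eps)
  xh <- (x - bcast_cn(matrix(mu, C, N), hw)) / bcast_cn(matrix(std, C, N), hw)
  dim(xh) <- d
  if (training) {
    m$cache_xhat <- xh
    m$cache_std <- std
  }
  y <- xh * bcast_cn(matrix(m$params$gamma$value, C, N), hw) +
    bcast_cn(matrix(m$params$beta$value, C, N), hw)
  dim(y) <- d
  y
}

#' @export
wn_backward.wn_bn <- function(m, dy) {
  d <- dim(dy)
  hw <- d[1] * d[2]
  C <- d[3]
  N <- d[4]
  xh <- m$cache_xhat
  dgamma <- channel_mean(dy * xh) * hw * N
  dbeta <- channel_mean(dy) * hw * N
  grad_add(m$params$gamma, dgamma)
  grad_add(m$params$beta, dbeta)
  # dx = gamma/std * (dy - mean(dy) - xhat * mean(dy * xhat)), means per channel
  mdy <- channel_mean(dy)
  mdyx <- channel_mean(dy * xh)
  coef <- m$params$gamma$value / m$cache_std
  dx <- (dy - bcast_cn(matrix(mdy, C, N), hw) -
           xh * bcast_cn(matrix(mdyx, C, N), hw)) *
    bcast_cn(matrix(coef, C, N), hw)
  dim(dx) <- d
  m$cache_xhat <- NULL
  dx
}

# -- activations ---------------------------------------------------------

relu_layer <- function() new_module("wn_relu")

#' @export
wn_forward.wn_relu <- function(m, x, training = FALSE) {
  y <- x * (x > 0)
  if (training) m$cache_mask <- x > 0
  y
}

#' @export
wn_backward.wn_relu <- function(m, dy) {
  dx <- dy * m$cache_mask
  m$cache_mask <- NULL
  dx
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# -- max pooling ---------------------------------------------------------

maxpool_layer <- function(k = 3, stride = 2, pad = 1) {
  new_module("wn_maxpool", k = as.integer(k), stride = as.integer(stride),
             pad = as.integer(pad))
}

#' @export
wn_forward.wn_maxpool <- function(m, x, training = FALSE) {
  r <- cpp_maxpool_forward(x, m$k, m$stride, m$pad)
  if (training) {
    m$cache_idx <- r$idx
    m$cache_xdim <- dim(x)
  }
  r$y
}

#' @export
wn_backward.wn_maxpool <- function(m, dy) {
  dx <- cpp_maxpool_backward(m$cache_idx, dy, m$cache_xdim)
  m$cache_idx <- NULL
  dx
}

# -- fully connected -----------------------------------------------------

linear_layer <- function(in_dim, out_dim) {
  new_module("wn_linear",
    in_dim = in_dim, out_dim = out_dim,
    params = list(
      W = wn_param(matrix(rnorm(out_dim * in_dim, sd = sqrt(2 / in_dim)),
                          out_dim, in_dim)),
      b = wn_param(numeric(out_dim))
    ))
}

#' @export
wn_forward.wn_linear <- function(m, x, training = FALSE) {
  if (training) m$cache_x <- x
  m$params$W$value %*% x + m$params$b$value
}

#' @export
wn_backward.wn_linear <- function(m, dy) {
  grad_add(m$params$W, dy %*% t(m$cache_x))
  grad_add(m$params$b, rowSums(dy))
  dx <- t(m$params$W$value) %*% dy
  m$cache_x <- NULL
  dx
}

# -- 1-D convolution across the channel axis (ECA-style) -----------------
#
# Input is a (C, N) matrix of channel descriptors; a single length-k filter
# is slid along the channel axis with zero padding, shared across channels
# and samples. No bias, matching the channel-attention lineage.

conv1d_layer <- function(k) {
  new_module("wn_conv1d", k = as.integer(k), pad = as.integer(k %/% 2),
             params = list(W = wn_param(rnorm(k, sd = sqrt(1 / k)))))
}

conv1d_apply <- function(xm, w, pad) {
  C <- nrow(xm)
  y <- matrix(0, C, ncol(xm))
  for (j in seq_along(w)) {
    src <- seq_len(C) + (j - 1L) - pad
    ok <- src >= 1L & src <= C
    y[ok, ] <- y[ok, , drop = FALSE] + w[j] * xm[src[ok], , drop = FALSE]
  }
  y
}

#' @export
wn_forward.wn_conv1d <- function(m, x, training = FALSE) {
  if (training) m$cache_x <- x
  conv1d_apply(x, m$params$W$value, m$pad)
}

#' @export
wn_backward.wn_conv1d <- function(m, dy) {
  xm <- m$cache_x
  C <- nrow(xm)
  k <- m$k
  dw <- numeric(k)
  dx <- matrix(0, C, ncol(xm))
  for (j in seq_len(k)) {
    src <- seq_len(C) + (j - 1L) - m$pad
    ok <- src >= 1L & src <= C
    dw[j] <- sum(dy[ok, , drop = FALSE] * xm[src[ok], , drop = FALSE])
    dx[src[ok], ] <- dx[src[ok], , drop = FALSE] +
      m$params$W$value[j] * dy[ok, , drop = FALSE]
  }
  grad_add(m$params$W, dw)
  m$cache_x <- NULL
  dx
}

# conv + BN + ReLU triple, the default unit everywhere in the backbone
cbr_module <- function(in_ch, out_ch, k, stride = 1) {
  seq_module(list(
    conv = conv2d_layer(in_ch, out_ch, k, stride),
    bn = bn_layer(out_ch),
    relu = relu_layer()
  ))
}
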