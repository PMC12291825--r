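# Backbone blocks: stem arithmetic, multi-order residual structure,
# feature-mask and channel-interaction invariants, full-network assembly.

test_that("stem halves the spatial side twice and rejects non-RGB input", {
  cfg <- tiny_config(input_size = 112)
  cfg$stem_channels <- 64L
  stem <- stem_module(cfg)
  x <- random_featuremap(112, 112, 3, 1, seed = 1)
  y <- wn_forward(stem, x)
  expect_equal(dim(y), c(28, 28, 64, 1))
  expect_error(wn_forward(stem, random_featuremap(112, 112, 4, 1)),
               "channels")
  # zero conv weights + zero bias: pre-BN conv output of any input is zero
  conv <- stem$children$conv
  conv$params$W$value <- conv$params$W$value * 0
  expect_true(all(wn_forward(conv, x) == 0))
})

test_that("multi-order block preserves shape and reduces to the identity when zeroed", {
  x <- random_featuremap(14, 14, 8, 2, seed = 2)
  blk <- multi_order_block(8, 8, 1, identity_module())
  expect_equal(dim(wn_forward(blk, x)), dim(x))
  # channel budget of the concatenation: C/4 + 3 * C/4 = C
  expect_equal(blk$q * 4, 8)
  # residual: zero branch weights (BN beta/gamma included) -> output == input
  zero_all_params(blk)
  expect_identical(wn_forward(blk, x, training = TRUE), x)
})

test_that("stride-2 multi-order block halves the spatial side", {
  x <- random_featuremap(16, 16, 8, 2, seed = 3)
  blk <- multi_order_block(8, 16, 2, identity_module())
  expect_equal(dim(wn_forward(blk, x)), c(8, 8, 16, 2))
  expect_error(multi_order_block(8, 10), "divisible by 4")
})

test_that("feature mask is strictly inside (0,1) and attenuates the input", {
  set.seed(8)
  fmm <- fmm_module()
  x <- random_featuremap(9, 9, 6, 2, seed = 4)
  y <- wn_forward(fmm, x, training = TRUE)
  mask <- fmm$cache_mask
  expect_true(all(mask > 0 & mask < 1))
  expect_true(all(abs(y) <= abs(x)))
  expect_equal(dim(y), dim(x))
  # zero input stays zero
  expect_true(all(wn_forward(fmm, x * 0) == 0))
  # constant input + zero-initialized conv: mask is sigmoid(0) = 0.5
  fmm0 <- fmm_module()
  zero_all_params(fmm0)
  xc <- array(0.7, c(5, 5, 4, 1))
  expect_equal(wn_forward(fmm0, xc), xc * 0.5, tolerance = 1e-12)
})

test_that("global interaction weights are a probability vector over channels", {
  cim <- cim_module(8, use_local = FALSE, use_global = TRUE)
  x <- random_featuremap(6, 6, 8, 3, seed = 5)
  w <- cim_channel_weights(cim, x)
  expect_equal(colSums(w$wg), rep(1, 3), tolerance = 1e-6)
  # equal channel norms -> uniform weights 1/C
  set.seed(12)
  base <- array(rnorm(4 * 4 * 2), c(4, 4, 2))
  xe <- array(0, c(4, 4, 8, 2))
  for (c in 1:8) xe[, , c, ] <- base * sample(c(-1, 1), 1)
  we <- cim_channel_weights(cim, xe)
  expect_equal(we$wg, matrix(1 / 8, 8, 2), tolerance = 1e-6)
})

test_that("local interaction weights match a hand-executed 1-D convolution", {
  cim <- cim_module(4, use_local = TRUE, use_global = FALSE)
  expect_equal(cim$children$conv1d$k, 3L)
  cim$children$conv1d$params$W$value <- c(0.1, 0.2, 0.3)
  # constant spatial maps make GAP return the channel values exactly
  x <- array(0, c(2, 2, 4, 1))
  for (c in 1:4) x[, , c, 1] <- c
  w <- cim_channel_weights(cim, x)
  # zero-padded conv of (1,2,3,4) with (0.1,0.2,0.3): (0.8, 1.4, 2.0, 1.1)
  expect_equal(as.vector(w$wl),
               c(0.6899744811, 0.8021838885, 0.8807970780, 0.7502601056),
               tolerance = 1e-9)
  # and against the scalar-loop oracle on random inputs up to 8 channels
  for (C in c(4, 6, 8)) {
    cimC <- cim_module(C, use_local = TRUE, use_global = FALSE)
    xr <- random_featuremap(3, 3, C, 2, seed = C)
    wr <- cim_channel_weights(cimC, xr)
    gap <- apply(xr, c(3, 4), mean)
    for (n in 1:2) {
      expect_equal(wr$wl[, n],
                   1 / (1 + exp(-oracle_conv1d(gap[, n],
                                               cimC$children$conv1d$params$W$value))),
                   tolerance = 1e-6)
    }
  }
})

test_that("full channel interaction preserves shape with no residual inside", {
  cim <- cim_module(8, TRUE, TRUE)
  x <- random_featuremap(5, 5, 8, 2, seed = 6)
  y <- wn_forward(cim, x, training = TRUE)
  expect_equal(dim(y), dim(x))
  # zeroing the fusion conv zeroes the output: nothing bypasses the module
  zero_all_params(cim$children$fuse_conv)
  zero_all_params(cim$children$fuse_bn)
  expect_true(all(wn_forward(cim, x, training = TRUE) == 0))
  expect_error(cim_module(7, TRUE, TRUE), "divisible by 2")
})

test_that("adaptive kernel size follows the channel count", {
  expect_identical(eca_kernel_size(64), 3L)
  expect_identical(eca_kernel_size(256), 5L)
  expect_identical(eca_kernel_size(1), 3L)
  for (C in c(2, 8, 32, 128, 512, 2048)) {
    k <- eca_kernel_size(C)
    expect_true(k %% 2 == 1 && k >= 3)
  }
})

test_that("network assembly follows the stage plan", {
  cfg <- tiny_config(num_identities = 3, input_size = 64,
                     blocks = c(1, 2, 1, 1))
  net <- build_wormnet(cfg, seed = 1)
  smry <- network_summary(net)
  # 64 -> stem /4 -> 16, stage2 and stage3 halve, stage4 keeps stride 1
  expect_equal(smry$height, c(16, 16, 8, 4, 4, 1))
  expect_equal(smry$channels[2:5], cfg$stage_channels)
  out <- wn_forward(net, random_featuremap(64, 64, 3, 2, seed = 7))
  expect_equal(dim(out$embedding), c(cfg$embedding_dim, 2))
  expect_equal(dim(out$logits), c(3, 2))
  expect_true(all(is.finite(out$embedding)))
  expect_error(wn_forward(net, random_featuremap(32, 32, 3, 1)), "expected input")
  expect_error(wormnet_config(stage_channels = c(16, 32, 64)), "4 entries")
  expect_error(wormnet_config(stage_channels = c(16, 32, 64, 66)),
               "divisible by 4")
})

test_that("blocks conserve shape at randomized sizes", {
  set.seed(11)
  for (r in 1:5) {
    h <- sample(5:12, 1)
    w <- sample(5:12, 1)
    C <- 4 * sample(1:4, 1)
    n <- sample(1:2, 1)
    x <- array(rnorm(h * w * C * n), c(h, w, C, n))
    for (m in list(multi_order_block(C, C, 1, identity_module()),
                   fmm_module(),
                   cim_module(C, TRUE, TRUE))) {
      expect_equal(dim(wn_forward(m, x)), dim(x))
    }
  }
})

test_that("every parameter receives gradient from a combined-loss backward", {
  cfg <- tiny_config(num_identities = 2, blocks = c(1, 2, 1, 1),
                     channels = c(8, 16, 16, 16))
  net <- build_wormnet(cfg, seed = 2)
  x <- random_featuremap(32, 32, 3, 4, seed = 8)
  labs <- c(1, 1, 2, 2)
  centers <- init_centers(cfg$embedding_dim, 1:2, seed = 5)
  ps <- wn_params(net)
  wormnet:::zero_grads(ps)
  out <- wn_forward(net, x, training = TRUE)
  lt <- wormnet:::triplet_loss_internal(out$embedding, labs, 0.3)
  lc <- wormnet:::center_loss_internal(out$embedding, labs, centers)
  li <- wormnet:::identity_loss_internal(out$logits, labs)
  wn_backward(net, list(dembedding = lt$grad + lc$grad, dlogits = li$grad))
  dead <- names(ps)[vapply(ps, function(p) is.null(p$grad) ||
                             all(p$grad == 0), logical(1))]
  expect_identical(dead, character(0))
})

test_that("identical images give identical embeddings in inference mode", {
  cfg <- tiny_config(num_identities = 2)
  net <- build_wormnet(cfg, seed = 3)
  x <- random_featuremap(32, 32, 3, 3, seed = 9)
  e1 <- extract_embedding(net, x)
  e2 <- extract_embedding(net, x)
  expect_identical(e1, e2)
  # batching is order-preserving
  e_batched <- extract_embedding(net, x, batch_size = 2)
  expect_equal(e_batched, e1, tolerance = 1e-12)
  expect_equal(nrow(e1), cfg$embedding_dim)
})
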