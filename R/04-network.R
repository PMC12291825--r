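#' Build the re-identification backbone
#'
#' Assembles the full network from a [wormnet_config()]: stem, four stages
#' of multi-order blocks (block counts `stage_block_counts`, widths
#' `stage_channels`), global average pooling to a one-dimensional
#' embedding, and a fully connected classification head over
#' `num_identities`. Within each stage the first block carries the spatial
#' feature-mask module as its interaction and the remaining blocks carry
#' the channel-interaction module; the ablation switches in the
#' configuration replace either with the identity. Spatial resolution
#' halves entering stages 2 and 3 (1x1 convolution with stride 2 on the
#' projection path); the final stage keeps stride `last_stage_stride`
#' (default 1).
#'
#' @param cfg a [wormnet_config()].
#' @param seed integer seed controlling weight initialization (He-normal
#'   convolutions, unit-gamma/zero-beta batch normalization, zero biases).
#' @return an object of class `wormnet_model` (also a module); run it with
#'   [wn_forward()] or [extract_embedding()].
#' @examples
#' cfg <- wormnet_config(input_size = 64, stem_channels = 8,
#'                       stage_block_counts = c(1, 1, 1, 1),
#'                       stage_channels = c(8, 16, 32, 64),
#'                       num_identities = 4)
#' net <- build_wormnet(cfg, seed = 1)
#' x <- array(rnorm(64 * 64 * 3), c(64, 64, 3, 1))
#' out <- wn_forward(net, x)
#' dim(out$logits) # 4 x 1
#' @export
build_wormnet <- function(cfg = wormnet_config(), seed = 1) {
  validate_config(cfg)
  with_seed(seed, {
    stages <- list()
    in_ch <- cfg$stem_channels
    for (s in 1:4) {
      blocks <- list()
      n_blocks <- cfg$stage_block_counts[s]
      out_ch <- cfg$stage_channels[s]
      for (j in seq_len(n_blocks)) {
        stride <- if (j == 1) {
          if (s %in% c(2, 3)) 2L else if (s == 4) cfg$last_stage_stride else 1L
        } else 1L
        inter <- if (j == 1) {
          if (cfg$use_fmm) fmm_module(cfg$fmm_kernel) else identity_module()
        } else {
          cim_module(out_ch, cfg$use_local_interaction,
                     cfg$use_global_interaction)
        }
        blocks[[paste0("block", j)]] <-
          multi_order_block(in_ch, out_ch, stride, inter, cfg$dw_kernel_sizes)
        in_ch <- out_ch
      }
      stages[[paste0("stage", s)]] <- seq_module(blocks)
    }
    net <- new_module(c("wormnet_model", "wn_seq"),
      cfg = cfg,
      children = c(
        list(stem = stem_module(cfg)),
        stages,
        list(classifier = linear_layer(cfg$embedding_dim, cfg$num_identities))
      ))
    net
  })
}

#' @export
print.wormnet_model <- function(x, ...) {
  cfg <- x$cfg
  cat("wormnet_model\n")
  print(cfg)
  cat(sprintf("  learnable parameters: %s\n",
              format(wn_n_params(x), big.mark = ",")))
  invisible(x)
}

#' Per-stage output shapes and parameter counts
#'
#' Structured build-time report: runs a single image through the network in
#' inference mode and records the output shape of the stem and of every
#' stage, together with per-component parameter counts.
#'
#' @param net a `wormnet_model`.
#' @return a data frame with columns `component`, `height`, `width`,
#'   `channels`, `n_params`.
#' @export
network_summary <- function(net) {
  cfg <- net$cfg
  x <- array(0, c(cfg$input_size, cfg$input_size, 3, 1))
  rows <- list()
  comps <- c("stem", paste0("stage", 1:4))
  for (nm in comps) {
    x <- wn_forward(net$children[[nm]], x, training = FALSE)
    rows[[nm]] <- data.frame(
      component = nm, height = dim(x)[1], width = dim(x)[2],
      channels = dim(x)[3],
      n_params = wn_n_params(net$children[[nm]]))
  }
  rows$classifier <- data.frame(
    component = "classifier", height = 1, width = 1,
    channels = cfg$num_identities,
    n_params = wn_n_params(net$children$classifier))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Forward pass of the full network
#'
#' @param m a `wormnet_model`.
#' @param x image array `(H, W, 3, N)` with `H = W = cfg$input_size`.
#' @param training logical; training mode caches intermediates and uses
#'   batch statistics in normalization layers.
#' @return list with `embedding` (`embedding_dim x N` matrix of pooled
#'   pre-classifier features), `logits` (`num_identities x N`) and
#'   `featuremap_dim` (dimensions of the final pre-pool feature map).
#' @export
wn_forward.wormnet_model <- function(m, x, training = FALSE) {
  cfg <- m$cfg
  if (length(dim(x)) != 4 || dim(x)[1] != cfg$input_size ||
      dim(x)[2] != cfg$input_size || dim(x)[3] != 3) {
    stop(sprintf("expected input of dim (%d, %d, 3, N), got (%s)",
                 cfg$input_size, cfg$input_size,
                 paste(dim(x), collapse = ", ")))
  }
  h <- wn_forward(m$children$stem, x, training)
  for (s in 1:4) h <- wn_forward(m$children[[paste0("stage", s)]], h, training)
  d <- dim(h)
  m$featuremap_dim <- d
  emb <- .cn_sums(h) / (d[1] * d[2])   # global average pooling -> (D, N)
  if (training) m$cache_prepool_dim <- d
  logits <- wn_forward(m$children$classifier, emb, training)
  list(embedding = emb, logits = logits, featuremap_dim = d)
}

#' Backward pass of the full network
#'
#' @param m a `wormnet_model` that has just run a training-mode forward.
#' @param dy list with `dembedding` and/or `dlogits` gradients matching the
#'   forward output shapes.
#' @return gradient with respect to the input image array, invisibly.
#' @export
wn_backward.wormnet_model <- function(m, dy) {
  demb <- dy$dembedding
  if (!is.null(dy$dlogits)) {
    dfc <- wn_backward(m$children$classifier, dy$dlogits)
    demb <- if (is.null(demb)) dfc else demb + dfc
  }
  d <- m$cache_prepool_dim
  hw <- d[1] * d[2]
  dh <- array(bcast_cn(demb / hw, hw), d)  # GAP backward
  for (s in 4:1) dh <- wn_backward(m$children[[paste0("stage", s)]], dh)
  invisible(wn_backward(m$children$stem, dh))
}

#' Extract L2-comparable embeddings
#'
#' Runs the network in inference mode (frozen batch-norm statistics, so
#' identical inputs give identical embeddings) and returns the pooled
#' pre-classifier vectors used for cosine-similarity retrieval.
#'
#' @param net a `wormnet_model`.
#' @param x image array `(H, W, 3, N)`.
#' @param batch_size images processed per forward pass.
#' @return `embedding_dim x N` matrix, one column per image, in input order.
#' @export
extract_embedding <- function(net, x, batch_size = 16) {
  if (length(dim(x)) == 3) dim(x) <- c(dim(x), 1)
  n <- dim(x)[4]
  out <- matrix(0, net$cfg$embedding_dim, n)
  for (start in seq(1, n, by = batch_size)) {
    ix <- start:min(start + batch_size - 1, n)
    out[, ix] <- wn_forward(net, x[, , , ix, drop = FALSE],
                            training = FALSE)$embedding
  }
  out
}

# ---- parameter (de)serialization --------------------------------------

get_param_values <- function(net) {
  lapply(wn_params(net), function(p) p$value)
}

set_param_values <- function(net, values) {
  ps <- wn_params(net)
  stopifnot(identical(sort(names(ps)), sort(names(values))))
  for (nm in names(ps)) ps[[nm]]$value <- values[[nm]]
  invisible(net)
}

get_bn_state <- function(net, prefix = "") {
  out <- list()
  if (inherits(net, "wn_bn")) {
    out[[sub("\\.$", "", prefix)]] <-
      list(mean = net$running_mean, var = net$running_var)
  }
  for (nm in names(net$children)) {
    out <- c(out, get_bn_state(net$children[[nm]], paste0(prefix, nm, ".")))
  }
  out
}

set_bn_state <- function(net, state, prefix = "") {
  if (inherits(net, "wn_bn")) {
    s <- state[[sub("\\.$", "", prefix)]]
    net$running_mean <- s$mean
    net$running_var <- s$var
  }
  for (nm in names(net$children)) {
    set_bn_state(net$children[[nm]], state, paste0(prefix, nm, "."))
  }
  invisible(net)
}
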