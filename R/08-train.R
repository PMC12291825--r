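# Training: identity-balanced PK batch sampling, Adam, step learning-rate
# schedule, per-step loss logging, final-iteration checkpointing.

#' Training configuration
#'
#' Defaults follow the standard re-identification recipe at mini-batch
#' size 16: 50 epochs of Adam (beta1 = 0.9, i.e. "momentum 0.9" in Adam's
#' first-moment sense) with weight decay 5e-4, base learning rate 3e-4 and
#' a step schedule that multiplies the rate by `lr_gamma = 0.1` at each of
#' the two `lr_milestones` (so the final rate is a tenth of a tenth of the
#' base when both fire). Batches are composed of `batch_p` identities times
#' `batch_k` instances (4 x 4 = 16 by default), which guarantees valid
#' triplets. No early stopping or best-epoch selection is performed: the
#' weights of the final iteration are the final model.
#'
#' @param epochs number of epochs.
#' @param batch_p,batch_k identities per batch and instances per identity;
#'   both must be >= 2.
#' @param base_lr base learning rate.
#' @param lr_milestones epochs after which the learning rate decays.
#' @param lr_gamma multiplicative decay per milestone.
#' @param weight_decay L2 weight decay coefficient.
#' @param beta1,beta2,adam_eps Adam moment parameters.
#' @param loss_weights weights of (triplet, center, identity) losses.
#' @param center_lr learning rate of the class-center update rule.
#' @param seed RNG seed controlling batch order.
#' @param verbose print per-epoch loss summaries.
#' @return a `train_config` list.
#' @export
train_config <- function(epochs = 50, batch_p = 4, batch_k = 4,
                         base_lr = 3e-4, lr_milestones = c(25, 40),
                         lr_gamma = 0.1, weight_decay = 5e-4,
                         beta1 = 0.9, beta2 = 0.999, adam_eps = 1e-8,
                         loss_weights = c(1, 1, 1), center_lr = 0.5,
                         seed = 1, verbose = FALSE) {
  stopifnot(batch_p >= 2, batch_k >= 2, epochs >= 0)
  structure(list(epochs = as.integer(epochs), batch_p = as.integer(batch_p),
                 batch_k = as.integer(batch_k), base_lr = base_lr,
                 lr_milestones = lr_milestones, lr_gamma = lr_gamma,
                 weight_decay = weight_decay, beta1 = beta1, beta2 = beta2,
                 adam_eps = adam_eps, loss_weights = loss_weights,
                 center_lr = center_lr, seed = as.integer(seed),
                 verbose = isTRUE(verbose)),
            class = "train_config")
}

#' Learning rate at a given epoch
#'
#' Closed-form step schedule: `base_lr * lr_gamma^(number of milestones
#' strictly below the epoch)`, epochs counted from 1.
#'
#' @param epoch epoch number (1-based).
#' @param cfg a [train_config()].
#' @return the learning rate.
#' @export
lr_schedule <- function(epoch, cfg) {
  cfg$base_lr * cfg$lr_gamma^sum(cfg$lr_milestones < epoch)
}

#' Identity-balanced PK batches for one epoch
#'
#' Composes mini-batches of exactly `P` identities times `K` instances.
#' Identities are shuffled and consumed in chunks of `P`, so every identity
#' appears at least once per epoch; a short final chunk is topped up with
#' identities drawn from the rest. Identities with fewer than `K` images
#' are sampled with replacement (flagged in the `with_replacement`
#' attribute). Deterministic given the seed.
#'
#' @param labels identity label of every training image.
#' @param P,K identities per batch / instances per identity.
#' @param seed RNG seed.
#' @return list of integer index vectors (length `P * K` each), with
#'   attribute `with_replacement` naming identities that needed
#'   replacement sampling.
#' @export
pk_sample <- function(labels, P, K, seed = 1) {
  ids <- unique(labels)
  if (length(ids) < P) {
    stop(sprintf("pk_sample: %d identities available, P = %d requested",
                 length(ids), P))
  }
  with_seed(seed, {
    ord <- sample(ids)
    batches <- list()
    replacement_ids <- character(0)
    chunks <- split(ord, ceiling(seq_along(ord) / P))
    for (chunk in chunks) {
      if (length(chunk) < P) {
        pool <- setdiff(ids, chunk)
        chunk <- c(chunk, sample(pool, P - length(chunk)))
      }
      batch <- integer(0)
      for (id in chunk) {
        ix <- which(labels == id)
        if (length(ix) >= K) {
          batch <- c(batch, ix[sample.int(length(ix), K)])
        } else {
          replacement_ids <- c(replacement_ids, as.character(id))
          batch <- c(batch, ix[sample.int(length(ix), K, replace = TRUE)])
        }
      }
      batches[[length(batches) + 1]] <- batch
    }
    attr(batches, "with_replacement") <- unique(replacement_ids)
    batches
  })
}

# ---- Adam --------------------------------------------------------------

adam_step <- function(params, lr, cfg, t) {
  b1 <- cfg$beta1
  b2 <- cfg$beta2
  for (p in params) {
    if (is.null(p$grad)) next
    g <- p$grad + cfg$weight_decay * p$value
    if (is.null(p$m)) {
      p$m <- g * 0
      p$v <- g * 0
    }
    p$m <- b1 * p$m + (1 - b1) * g
    p$v <- b2 * p$v + (1 - b2) * g * g
    mhat <- p$m / (1 - b1^t)
    vhat <- p$v / (1 - b2^t)
    p$value <- p$value - lr * mhat / (sqrt(vhat) + cfg$adam_eps)
  }
  invisible(params)
}

first_nonfinite <- function(values) {
  for (nm in names(values)) {
    if (!all(is.finite(values[[nm]]))) return(nm)
  }
  NULL
}

#' Train the network
#'
#' Full training loop: loads the training split (resized to the model's
#' input size, standardized with training-split channel statistics),
#' iterates PK-sampled batches through forward pass, combined
#' triplet + center + identity loss, backpropagation and an Adam step with
#' the step learning-rate schedule, updates the class centers with the
#' delta rule, and returns the final-iteration weights (no best-epoch
#' selection). Aborts with a diagnostic naming the first non-finite
#' quantity if the loss diverges.
#'
#' @param net a `wormnet_model` whose `num_identities` matches the number
#'   of training identities in `dataset`.
#' @param dataset a `reid_dataset` with a train split.
#' @param cfg a [train_config()].
#' @return a checkpoint object (class `wormnet_checkpoint`): list with
#'   `version`, `cfg` (model config), `train_cfg`, `params`, `bn_state`,
#'   `centers`, `stats` (image normalization statistics), `class_ids`, and
#'   `log` (per-step data frame with loss components and learning rate).
#' @export
train_wormnet <- function(net, dataset, cfg = train_config()) {
  mcfg <- net$cfg
  train_rows <- dataset$manifest[dataset$manifest$split == "train", ]
  if (nrow(train_rows) == 0) stop("dataset has no train split")
  class_ids <- sort(unique(train_rows$identity))
  if (length(class_ids) != mcfg$num_identities) {
    stop(sprintf("model expects %d identities, train split has %d",
                 mcfg$num_identities, length(class_ids)))
  }
  x_all <- load_images(file.path(dataset$dir, train_rows$file),
                       size = mcfg$input_size)
  stats <- image_stats(x_all)
  x_all <- normalize_images(x_all, stats)
  labels <- train_rows$identity

  centers <- init_centers(mcfg$embedding_dim, class_ids,
                          seed = derive_seed(cfg$seed, 77L))
  params <- wn_params(net)
  log_rows <- list()
  t_global <- 0
  for (epoch in seq_len(cfg$epochs)) {
    lr <- lr_schedule(epoch, cfg)
    batches <- pk_sample(labels, cfg$batch_p, cfg$batch_k,
                         seed = derive_seed(cfg$seed, epoch))
    for (b in seq_along(batches)) {
      ix <- batches[[b]]
      xb <- x_all[, , , ix, drop = FALSE]
      yb <- labels[ix]
      zero_grads(params)
      out <- wn_forward(net, xb, training = TRUE)

      lt <- triplet_loss_internal(out$embedding, yb, mcfg$triplet_margin)
      lc <- center_loss_internal(out$embedding, yb, centers)
      li <- identity_loss_internal(out$logits, yb, class_ids)
      w <- cfg$loss_weights
      total <- total_loss(lt$loss, lc$loss, li$loss, w)
      if (!is.finite(total)) {
        bad <- first_nonfinite(list(triplet = lt$loss, center = lc$loss,
                                    identity = li$loss,
                                    embedding = out$embedding,
                                    logits = out$logits))
        stop(sprintf(
          "training diverged at epoch %d step %d: first non-finite tensor: %s",
          epoch, b, bad))
      }
      wn_backward(net, list(
        dembedding = w[1] * lt$grad + w[2] * lc$grad,
        dlogits = w[3] * li$grad))
      t_global <- t_global + 1
      adam_step(params, lr, cfg, t_global)
      centers <- update_centers(centers, out$embedding, yb, cfg$center_lr)
      log_rows[[t_global]] <- data.frame(
        epoch = epoch, step = b, lr = lr, triplet = lt$loss,
        center = lc$loss, identity = li$loss, total = total)
    }
    if (cfg$verbose) {
      ep <- do.call(rbind, log_rows[vapply(log_rows, function(r)
        r$epoch == epoch, logical(1))])
      message(sprintf(
        "epoch %3d  lr %.2e  triplet %.4f  center %.2f  id %.4f  total %.3f",
        epoch, lr, mean(ep$triplet), mean(ep$center), mean(ep$identity),
        mean(ep$total)))
    }
  }
  log <- if (length(log_rows) > 0) do.call(rbind, log_rows) else
    data.frame(epoch = integer(0), step = integer(0), lr = numeric(0),
               triplet = numeric(0), center = numeric(0),
               identity = numeric(0), total = numeric(0))
  structure(list(
    version = 1L, cfg = mcfg, train_cfg = cfg,
    params = get_param_values(net), bn_state = get_bn_state(net),
    centers = centers, stats = stats, class_ids = class_ids, log = log
  ), class = "wormnet_checkpoint")
}

#' Save a checkpoint to a single file
#'
#' Serialized weights plus the embedded model configuration (versioned
#' schema), restorable with [load_checkpoint()].
#'
#' @param checkpoint a `wormnet_checkpoint` from [train_wormnet()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(checkpoint, path) {
  stopifnot(inherits(checkpoint, "wormnet_checkpoint"))
  saveRDS(checkpoint, path)
  invisible(path)
}

#' Restore a model from a checkpoint file
#'
#' @param path file written by [save_checkpoint()] (or a checkpoint
#'   object).
#' @return list with `net` (rebuilt `wormnet_model` carrying the restored
#'   weights and batch-norm state) and `checkpoint`.
#' @export
load_checkpoint <- function(path) {
  ckpt <- if (inherits(path, "wormnet_checkpoint")) path else readRDS(path)
  if (!identical(ckpt$version, 1L)) {
    stop("unsupported checkpoint schema version: ", ckpt$version)
  }
  net <- build_wormnet(ckpt$cfg, seed = 1)
  set_param_values(net, ckpt$params)
  set_bn_state(net, ckpt$bn_state)
  list(net = net, checkpoint = ckpt)
}

#' Embed a dataset split
#'
#' @param net a trained `wormnet_model`.
#' @param dataset a `reid_dataset`.
#' @param split `"train"`, `"gallery"` or `"query"`.
#' @param stats normalization statistics from the checkpoint.
#' @param batch_size forward-pass batch size.
#' @return an [embedding_set()] (role `"query"` for the query split, else
#'   `"gallery"`).
#' @export
embed_split <- function(net, dataset, split, stats, batch_size = 16) {
  rows <- dataset$manifest[dataset$manifest$split == split, ]
  if (nrow(rows) == 0) stop("dataset has no '", split, "' split")
  x <- load_images(file.path(dataset$dir, rows$file),
                   size = net$cfg$input_size)
  x <- normalize_images(x, stats)
  v <- extract_embedding(net, x, batch_size)
  embedding_set(v, rows$identity,
                role = if (split == "query") "query" else "gallery",
                source_id = rows$file)
}

#' Cache embeddings as a columnar file
#'
#' Plain CSV with columns `id`, `label`, then the embedding coordinates;
#' re-loadable with [read_embeddings()] for re-evaluation without
#' re-extraction.
#'
#' @param es an [embedding_set()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_embeddings <- function(es, path) {
  df <- data.frame(id = es$source_id, label = es$labels,
                   t(es$vectors), check.names = FALSE)
  colnames(df) <- c("id", "label", paste0("v", seq_len(nrow(es$vectors))))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read cached embeddings
#'
#' @param path CSV written by [write_embeddings()].
#' @param role `"gallery"` or `"query"`.
#' @return an [embedding_set()].
#' @export
read_embeddings <- function(path, role = "gallery") {
  df <- utils::read.csv(path, check.names = FALSE)
  embedding_set(t(as.matrix(df[, -(1:2), drop = FALSE])), df$label,
                role = role, source_id = df$id)
}
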