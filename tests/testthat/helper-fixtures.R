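# Shared fixtures. Datasets are generated once per test run and cached in
# this environment; all sizes are desk-scale so the whole suite stays fast.

.fixtures <- new.env(parent = emptyenv())

# reduced backbone used wherever a trainable network is needed
tiny_config <- function(num_identities = 2, input_size = 32,
                        blocks = c(1, 1, 1, 1), channels = c(16, 32, 32, 64),
                        ...) {
  wormnet_config(input_size = input_size, stem_channels = 8,
                 stage_block_counts = blocks, stage_channels = channels,
                 num_identities = num_identities, ...)
}

# 2 train + 2 test identities, 8 images each: the overfit sanity set
tiny_dataset <- function() {
  if (is.null(.fixtures$tiny_ds)) {
    .fixtures$tiny_ds <- generate_dataset(
      n_train_ids = 2, n_test_ids = 2, images_per_id = 8, queries_per_id = 2,
      difficulty = 0.3, seed = 1,
      dir = file.path(tempdir(), "wormnet-tiny-ds"))
  }
  .fixtures$tiny_ds
}

# small-scale training recipe: tiny runs get few optimizer steps, so the
# base rate is raised and the center term uses the downweighted convention
tiny_train_config <- function(epochs = 30, seed = 1, ...) {
  train_config(epochs = epochs, batch_p = 2, batch_k = 4, base_lr = 1e-2,
               lr_milestones = c(15, 25), loss_weights = c(1, 5e-4, 1),
               seed = seed, ...)
}

# set every learnable parameter of a module (tree) to zero
zero_all_params <- function(m) {
  for (p in wn_params(m)) p$value <- p$value * 0
  invisible(m)
}

random_featuremap <- function(h, w, c, n, seed = 1) {
  set.seed(seed)
  array(rnorm(h * w * c * n), c(h, w, c, n))
}
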