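# wormnet

Re-identification (ReID) of elongated, arbitrarily posed animals —
silkworm larvae in particular — from top-down images. Given a *query*
image of an individual, the task is to retrieve every image of the same
individual from a *gallery*, with training and evaluation identities kept
disjoint. Unlike pedestrians, larvae lie parallel, perpendicular or tilted
at arbitrary angles, look nearly identical to one another, and sit on
cluttered rearing-box backgrounds, which defeats off-the-shelf person-ReID
backbones. This package provides, entirely in R (with Rcpp/Armadillo
convolution kernels — forward *and* backward passes are implemented
natively, so the whole pipeline runs on one CPU):

- a residual convolutional backbone built from **multi-order extraction
  blocks**: the input is aggregated by two 1×1 convolutions into two
  C/4-channel sub-features, one kept as an identity branch and one passed
  through parallel depth-wise convolutions at kernel sizes 3×3, 5×5 and
  7×7; the four C/4-wide maps are concatenated, passed through an
  interaction module `Inter`, and added back to the block input:
  `Output = X + Inter(Concat(X₁, DW₇(X₂), DW₅(X₂), DW₃(X₂)))`;
- a **feature mask module (FMM)** for spatial purification:
  `Y = σ(Conv₇ₓ₇(Concat(AvgPoolc(X), MaxPoolc(X)))) ⊙ X`, a single-channel
  sigmoid mask built from per-pixel channel statistics;
- a **channel interaction module (CIM)** combining a *local* branch
  (channel attention: sigmoid-activated 1-D convolution over pooled
  channel descriptors, kernel size adapted to the channel count) and a
  *global* branch (divisive normalization by channel L2 norms,
  `Wg_i = ‖X_i‖₂ / Σ_j ‖X_j‖₂`), fused by concatenation and a 1×1
  convolution;
- the standard metric-learning objective
  `L = L_triplet + L_center + L_ID`, with batch-hard triplet mining under
  cosine distance (`max(0, d_p − d_n + α)`, α = 0.3), center loss
  `½ Σ‖f_j − c_{y_j}‖²`, and softmax cross-entropy, trained with
  identity-balanced P×K batches and Adam;
- cosine-similarity retrieval evaluation (**mAP** and **CMC** at ranks
  1/5/10), verified in the test suite against a definition-literal
  brute-force oracle, plus frame-coded top-k retrieval panels;
- a **synthetic worm-image generator** producing identity-consistent,
  seed-deterministic 224×224 images (tapered tubes along random curves
  with identity-specific size, coloring and band markings, background
  clutter, uniform padding) in the Market1501-style
  `bounding_box_train` / `bounding_box_test` / `query` layout, with a
  difficulty knob controlling inter-identity separation. Any real dataset
  in the same layout is consumable by the same loaders.

At full scale the default configuration follows the 3:4:6:3 stage plan
with widths 256/512/1024/2048: a 224×224×3 image maps to a 56×56×64 stem
output and a 14×14×2048 final feature map, pooled to a 2048-dimensional
embedding.

## Worked example

```r
library(wormnet)

# 1. generate a synthetic dataset: 8 training + 4 test identities
ds <- generate_dataset(n_train_ids = 8, n_test_ids = 4, images_per_id = 12,
                       queries_per_id = 3, difficulty = 0.2, seed = 42,
                       dir = file.path(tempdir(), "worms"))
print(ds)
#> reid_dataset at /tmp/.../worms
#>   gallery    36 images,   4 identities
#>   query      12 images,   4 identities
#>   train      96 images,   8 identities

# 2. build a desk-scale backbone and train it
cfg <- wormnet_config(input_size = 64, stem_channels = 16,
                      stage_block_counts = c(1, 1, 1, 1),
                      stage_channels = c(16, 32, 64, 128),
                      num_identities = 8)
net <- build_wormnet(cfg, seed = 42)
res <- train_and_evaluate(net, ds, train_config(
  epochs = 30, base_lr = 1e-2, lr_milestones = c(15, 25),
  loss_weights = c(1, 5e-4, 1), seed = 42))

# 3. retrieval quality on the four held-out identities
print(res$report)
#> Retrieval evaluation: 12 queries vs 36 gallery images
#>   mAP: 0.8046
#>   CMC rank1: 0.7500
#>   CMC rank5: 1.0000
#>   CMC rank10: 1.0000

# 4. the raw-pixel nearest-neighbor floor on the same split
pixel_nn_baseline(ds)$cmc[["rank1"]]
#> [1] 0.5833333
```

The trained embedding ranks three quarters of the held-out queries
correctly at rank 1 (every query is solved by rank 5), versus 0.58 for
raw pixels — the learned representation generalizes to identities never
seen in training. Mind that this is a 27k-parameter model trained for 30
epochs on 96 images; accuracy rises quickly with dataset size, input
resolution and training length (see `scripts/acceptance.R` for a larger
run).

A command-line interface wrapping the same functions is installed at
`exec/wormnet`:

```sh
Rscript <pkglib>/wormnet/exec/wormnet generate --out worms --ids 20 --seed 1
Rscript <pkglib>/wormnet/exec/wormnet train --data worms --out model.rds
Rscript <pkglib>/wormnet/exec/wormnet evaluate --checkpoint model.rds --data worms --out report.json
Rscript <pkglib>/wormnet/exec/wormnet visualize --checkpoint model.rds --data worms --out panels/
Rscript <pkglib>/wormnet/exec/wormnet ablate --data worms --out ablation.json
```

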