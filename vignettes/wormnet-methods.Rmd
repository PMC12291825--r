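---
title: "Methods: multi-order networks for larva re-identification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-order networks for larva re-identification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the model, the design decisions taken where the
architecture family leaves choices open, the synthetic data the package
tests itself on, and the numerical conventions. It states no empirical
result beyond what the test suite and `scripts/acceptance.R` compute.

## The problem

Re-identification treats recognition as retrieval: embed images into a
vector space, then rank a gallery by cosine similarity to a query and
hope that images of the same individual come out on top. Training and
evaluation identities are disjoint, so the network must learn *features
that transfer* (body proportions, coloring, marking patterns) rather
than a fixed classification. Larvae are a hard instance: elongated
bodies at arbitrary orientations and bends, very high inter-individual
similarity, and cluttered backgrounds.

## The backbone

The network is a four-stage residual pipeline: a stem (7×7 convolution,
stride 2, batch norm + ReLU, then 3×3 max pooling, stride 2 — each
halving the spatial side), stages of *multi-order blocks* with block
counts 3:4:6:3 and widths 256/512/1024/2048 at full scale, global
average pooling into the embedding, and a fully connected identity
classifier used only by the training objective. Spatial resolution
halves at the entries of stages 2 and 3 and is kept in stage 4 (stride
1), so 224 → 56 (stem) → 56 → 28 → 14 → 14.

**Multi-order block.** Two parallel 1×1 convolutions aggregate the input
into two sub-features of a *quarter* of the output width; a half split
would need an extra 1×1 after concatenation, and compressing further
loses information. One sub-feature is the identity branch; the other is
processed by three parallel *depth-wise* convolutions at 3×3, 5×5 and
7×7 — three granularities at per-channel cost. Each convolution carries
batch norm and ReLU. Concatenating the four C/4-wide maps restores C
channels; an interaction module is applied; and the block input is added
back (1×1 projection with matching stride where the shape changes). We
implement the depth-wise convolutions without a pointwise stage: channel
mixing is already provided by the surrounding 1×1 convolutions and the
concatenation, and the point of depth-wise kernels here is parameter
reduction.

**Feature mask module (FMM).** Spatial attention from channel
statistics: per-pixel mean and maximum over channels are concatenated
into a two-channel map, convolved 7×7, and squashed by a sigmoid into a
single-channel mask in (0, 1) that multiplies the feature map. The mask
can only attenuate, never amplify — it purifies (suppresses background
responses) rather than re-scores. Within each stage the FMM follows the
*first* block; the remaining blocks carry the channel-interaction
module.

**Channel interaction module (CIM).** Two 1×1 convolutions aggregate C
channels into two C/2-channel sub-features (widths are our choice: C/2
per branch makes the final concatenation return exactly C channels
before the fusing 1×1). The *local* branch pools each channel to one
number, slides a shared 1-D convolution along the channel axis — kernel
size from the channel count via the adaptive-odd rule
`k = odd(floor(|log2(C)/2 + 1/2|))`, minimum 3, the convention of the
channel-attention lineage this branch follows — and applies a sigmoid;
the weights rescale the sub-feature per channel. The *global* branch
represents each channel by its L2 norm and divides by the sum of norms,
so the weights form a probability vector over channels (an ε = 1e-6 in
the denominator guards the all-zero input; norms are nonnegative, no
absolute value is needed, and there is no learnable affine). The texts
of this module family name a "δ activation" but write sigmoid in the
formula; we implement sigmoid. Concatenation and a 1×1 convolution
(batch norm, *no* ReLU — a ReLU here would clip recalibrated features
before the residual addition in the surrounding block) fuse the two
recalibrated sub-features. The CIM itself has no residual connection;
the multi-order block owns the residual.

**Ablation switches.** Three independent flags span the ablation
lattice: `use_fmm`, `use_local_interaction`, `use_global_interaction`.
With a single channel flag the corresponding branch is applied to the
full C channels (pure channel attention, or pure divisive
normalization) — exactly how the module decomposes in ablation studies;
with neither, the interaction is the identity and the block is a pure
multi-order extractor.

## Losses and training

The objective is the unweighted sum of three terms (weights are
configurable):

- **Batch-hard triplet loss**, cosine distance `d = 1 − cos`: per anchor
  the most distant positive and closest negative within the mini-batch
  feed `max(0, d_p − d_n + α)`, α = 0.3. We read the distance as plain
  `1 − cos`; mining follows the batch-hard convention with P×K batches
  (P identities × K instances, default 4×4 = 16), which guarantees every
  anchor a positive and a negative.
- **Center loss** `½ Σ‖f_j − c_{y_j}‖²` on *raw* (unnormalized)
  embeddings; normalization enters only inside cosine computations.
  Centers are updated by the standard per-batch delta rule
  (`c ← c − 0.5 · Σ(c − f)/(1 + n)`), outside the network's gradient.
- **Identity loss**: mean softmax cross-entropy of the classifier
  logits. (Written as a plain sum in some formulations; the mean is the
  universal convention and is what makes "uniform logits → log K" hold.)

Training uses Adam (β₁ = 0.9 — "momentum 0.9" in Adam's first-moment
sense, as Adam has no classical momentum), weight decay 5e-4, base
learning rate 3e-4, 50 epochs, and a step schedule that multiplies the
rate by 0.1 after epochs 25 and 40 (two decay steps; the published
recipe's "decay factor 2, final rate 0.1" is ambiguous — we read it as
two ×0.1 steps, fully config-overridable, and the schedule is logged so
any comparison to published dynamics stays qualitative). The weights of
the final iteration are the final model; no best-epoch selection.
Images are scaled to [0, 1] and standardized per channel with statistics
computed from the training split (models are trained from scratch, so no
external normalization constants exist). Initialization is He-normal for
convolutions, γ = 1/β = 0 for batch norm, zero biases, all under a
caller-supplied seed. Inference freezes batch-norm statistics, so
identical inputs give identical embeddings.

## Evaluation protocol

Cosine-similarity ranking with ties broken by ascending gallery index
(deterministic results). Average precision is *exact* — the mean of
precision at each rank where a correct match occurs — not interpolated;
mAP averages over queries; CMC(k) is the fraction of queries whose first
hit is within rank k. Camera-aware filtering (dropping same-camera
gallery entries, as in the pedestrian protocol) is off by default: the
larva setting has no camera-identity structure in evaluation. Queries
whose identity is absent from the gallery are excluded with a warning.
The test suite pins the implementation to a definition-literal
brute-force recomputation to 1e-9 over random instances.

## The synthetic generator

Real larva corpora are not redistributable, so the package carries a
generator that emulates the *structure* of such a dataset: one worm per
image, rendered as a soft-edged tapered tube along a random low-order
curvature profile (orientation uniform in [0, 2π), bend coefficients
drawn per sample within the identity's curvature range), with
identity-fixed length, width, hue/saturation/value, and a sinusoidal
segment-band marking pattern; background clutter from random Gaussian
blobs and streaks; the natural-size crop is padded symmetrically with a
uniform mid-gray to 224×224. Rendering is bit-reproducible given
(identity, pose seed). A *difficulty* knob in [0, 1] interpolates the
identity parameters between maximal spread (evenly spaced hues, wide
size range) and a common greenish larva with small jitter; the test
suite checks that raw-pixel nearest-neighbor rank-1 decreases
monotonically in this knob (averaged over 5 seeds).

What the generator does *not* emulate: real textures and lighting,
occlusion by neighboring worms, frass and box-edge artifacts, growth
between recording sessions. Passing tests on synthetic data therefore
demonstrate that the architecture, losses, optimization and evaluation
stack are correct and that the network can learn transferable identity
features — not that any particular accuracy carries over to real
rearing-box footage.

## Problem sizes and the small-scale recipe

The default configuration (224 px, 3:4:6:3, widths up to 2048, ~41M
parameters) is exercised forward-only in the tests, verifying the stage
arithmetic. Trainable tests use reduced configurations — 32–64 px
inputs, one or two blocks per stage, widths 8–128 — which train in
seconds to a minute on one CPU:

- *Overfit sanity*: 2 identities × 8 images, 30 epochs, 3 seeds;
  training-set retrieval rank-1 is expected to reach 1.
- *Generalization*: 20 training / 10 held-out identities × 20 images at
  difficulty 0; the trained network's query rank-1 is compared against
  the raw-pixel nearest-neighbor baseline.

Tiny runs get only tens of optimizer steps, where the full-scale recipe
(3e-4 over thousands of steps) barely moves a fresh network. The
package's small-scale recipe therefore raises the base rate to 1e-2,
scales the decay milestones to the run length, and uses the downweighted
center-loss convention (1, 5e-4, 1) so that tens of steps are not
dominated by the pull toward freshly initialized random centers. The
full-scale defaults in `train_config()` are unchanged.

## Numerical choices and degenerate inputs

- Convolution padding is `kernel %/% 2` everywhere ("same"-style), which
  is what makes the 224 → 56 → 28 → 14 arithmetic exact.
- Batch-norm ε = 1e-5; variance clamped at 0 before the square root.
- CIM global branch: ε = 1e-6 in the weight denominator; channel-norm
  gradients guard division by `max(‖·‖, 1e-12)`.
- Zero-norm embeddings are rejected by name in similarity computations
  (a zero vector has no direction).
- Ranking ties break by ascending gallery index; `max.col` ties in the
  FMM channel-max break to the first channel.
- Training aborts with a diagnostic naming the first non-finite tensor
  if any loss component diverges.
- Identities with fewer than K images are PK-sampled with replacement
  and flagged on the batch list.

## Known limitations

- Pure-R/BLAS execution: full-scale (224 px) *training* is out of reach
  on one CPU; the full configuration is validated structurally and
  forward-only. The engine is exact (finite-difference checks to 1e-5
  through every block) but not fast.
- The single-file checkpoint stores weights with an embedded config and
  schema version; it is an RDS artifact, not a portable exchange format.
- The generator's clutter model is a stand-in; background statistics of
  real rearing boxes are unknown and tunable only qualitatively.
- JPEG input is supported through the image I/O backend, but the
  generator emits PNG only.
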