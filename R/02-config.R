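#' Architecture configuration
#'
#' Builds the hyper-parameter record for the backbone. The defaults
#' reproduce the full-scale network: a 7x7 stem to 64 channels, four stages
#' of multi-order blocks with stage ratio 3:4:6:3 and widths
#' 256/512/1024/2048, spatial downsampling (stride 2) entering stages 2 and
#' 3, stride 1 in the last stage, and a 2048-dimensional pooled embedding.
#' A 224x224x3 input therefore maps to a 56x56x64 stem output and a
#' 14x14x2048 final-stage feature map.
#'
#' Three structural switches control the interaction modules and span the
#' ablation lattice: `use_fmm` (spatial feature mask after the first block
#' of each stage), `use_local_interaction` (channel attention via 1-D
#' convolution over pooled channel descriptors) and
#' `use_global_interaction` (L2-norm divisive channel normalization). When
#' both channel flags are on, the blocks after the first in each stage
#' carry the full dual-branch channel-interaction module; with one flag the
#' corresponding single branch is applied to the full channel width; with
#' neither the interaction is the identity.
#'
#' The channel split fraction of the multi-order block (1/4), the parallel
#' depth-wise kernel sizes (3/5/7) and the mask-module kernel (7) are fixed
#' properties of the architecture, not tunables.
#'
#' @param input_size input image side in pixels (images are square).
#' @param stem_channels channels produced by the stem.
#' @param stage_block_counts integer vector of 4 block counts per stage.
#' @param stage_channels integer vector of 4 stage widths; each must be
#'   divisible by 4 (the 1/4 channel split) and the last one is the
#'   embedding dimension.
#' @param triplet_margin margin of the triplet hinge (default 0.3).
#' @param use_fmm,use_local_interaction,use_global_interaction structural
#'   switches, see Details.
#' @param last_stage_stride stride of the final stage (default 1, which
#'   keeps the 14x14 resolution at full scale).
#' @param num_identities number of training identities (classifier width).
#' @return an object of class `wormnet_config`.
#' @examples
#' cfg <- wormnet_config(num_identities = 5)
#' cfg$embedding_dim # 2048
#' @export
wormnet_config <- function(input_size = 224,
                           stem_channels = 64,
                           stage_block_counts = c(3, 4, 6, 3),
                           stage_channels = c(256, 512, 1024, 2048),
                           triplet_margin = 0.3,
                           use_fmm = TRUE,
                           use_local_interaction = TRUE,
                           use_global_interaction = TRUE,
                           last_stage_stride = 1,
                           num_identities = 10) {
  cfg <- list(
    input_size = as.integer(input_size),
    stem_channels = as.integer(stem_channels),
    stage_block_counts = as.integer(stage_block_counts),
    stage_channels = as.integer(stage_channels),
    split_fraction = 1 / 4,
    dw_kernel_sizes = c(3L, 5L, 7L),
    fmm_kernel = 7L,
    triplet_margin = triplet_margin,
    use_fmm = isTRUE(use_fmm),
    use_local_interaction = isTRUE(use_local_interaction),
    use_global_interaction = isTRUE(use_global_interaction),
    last_stage_stride = as.integer(last_stage_stride),
    num_identities = as.integer(num_identities)
  )
  cfg$embedding_dim <- cfg$stage_channels[4]
  class(cfg) <- "wormnet_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  if (length(cfg$stage_block_counts) != 4) {
    stop("stage_block_counts must have exactly 4 entries")
  }
  if (length(cfg$stage_channels) != 4) {
    stop("stage_channels must have exactly 4 entries")
  }
  if (any(cfg$stage_channels %% 4 != 0)) {
    stop("every stage_channels entry must be divisible by 4 (1/4 channel split)")
  }
  if (any(cfg$stage_block_counts < 1)) stop("stage_block_counts must be >= 1")
  if (cfg$input_size < 32) stop("input_size must be at least 32 pixels")
  if (cfg$stem_channels < 1) stop("stem_channels must be positive")
  if (cfg$num_identities < 1) stop("num_identities must be positive")
  if (!cfg$last_stage_stride %in% c(1L, 2L)) {
    stop("last_stage_stride must be 1 or 2")
  }
  invisible(cfg)
}

#' @export
print.wormnet_config <- function(x, ...) {
  cat("wormnet_config\n")
  cat(sprintf("  input: %dx%dx3   stem: %d channels\n",
              x$input_size, x$input_size, x$stem_channels))
  cat(sprintf("  stages: blocks %s, channels %s\n",
              paste(x$stage_block_counts, collapse = ":"),
              paste(x$stage_channels, collapse = "/")))
  cat(sprintf("  interactions: fmm=%s local=%s global=%s\n",
              x$use_fmm, x$use_local_interaction, x$use_global_interaction))
  cat(sprintf("  embedding dim: %d   identities: %d   margin: %.2f\n",
              x$embedding_dim, x$num_identities, x$triplet_margin))
  invisible(x)
}

config_fields <- c(
  "input_size", "stem_channels", "stage_block_counts", "stage_channels",
  "triplet_margin", "use_fmm", "use_local_interaction",
  "use_global_interaction", "last_stage_stride", "num_identities"
)

#' Read an architecture configuration from YAML
#'
#' The file must mirror [wormnet_config()] field-for-field; unknown keys are
#' rejected rather than silently dropped.
#'
#' @param path YAML file path.
#' @return a `wormnet_config`.
#' @export
config_from_yaml <- function(path) {
  vals <- yaml::read_yaml(path)
  unknown <- setdiff(names(vals), config_fields)
  if (length(unknown) > 0) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  }
  do.call(wormnet_config, vals)
}

#' Write an architecture configuration to YAML
#'
#' @param cfg a `wormnet_config`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
config_to_yaml <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg)[config_fields], path)
  invisible(path)
}

#' Adaptive kernel size for channel attention
#'
#' Kernel size of the 1-D convolution used by the local channel-interaction
#' branch, chosen from the channel count by the adaptive-odd-kernel rule of
#' the ECA lineage: the nearest odd integer to `|log2(C)/2 + 1/2|`
#' (floor-then-make-odd), with a minimum of 3.
#'
#' @param C channel count (>= 1).
#' @return an odd integer kernel size.
#' @examples
#' eca_kernel_size(64)  # 3
#' eca_kernel_size(256) # 5
#' @export
eca_kernel_size <- function(C) {
  stopifnot(C >= 1)
  t <- floor(abs(log2(C) / 2 + 0.5))
  k <- if (t %% 2 == 1) t else t + 1
  as.integer(max(k, 3))
}
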