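#' @useDynLib wormnet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif setNames
NULL

# ---- parameters --------------------------------------------------------
#
# A parameter is a tiny mutable cell (environment) holding the value, its
# accumulated gradient, and the Adam moments. Modules hold named lists of
# these; the optimizer walks the flattened list.

wn_param <- function(value) {
  p <- new.env(parent = emptyenv())
  p$value <- value
  p$grad <- NULL
  class(p) <- "wn_param"
  p
}

grad_add <- function(p, g) {
  p$grad <- if (is.null(p$grad)) g else p$grad + g
  invisible(p)
}

zero_grads <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(params)
}

# ---- module base -------------------------------------------------------
#
# A module is an environment with optional fields `params` (named list of
# wn_param) and `children` (named list of modules). Forward passes cache
# whatever the backward pass needs inside the module environment; the
# training loop is single-threaded, so this is safe.

new_module <- function(cls, ...) {
  m <- new.env(parent = emptyenv())
  fields <- list(...)
  for (nm in names(fields)) assign(nm, fields[[nm]], envir = m)
  if (is.null(m$params)) m$params <- list()
  if (is.null(m$children)) m$children <- list()
  class(m) <- c(cls, "wn_module")
  m
}

#' Run a module's forward pass
#'
#' Generic dispatcher over the package's building blocks (stem, multi-order
#' block, feature-mask module, channel-interaction module, full network, and
#' the primitive layers they are assembled from).
#'
#' @param m a module created by one of the constructors such as
#'   [stem_module()], [multi_order_block()], [fmm_module()], [cim_module()]
#'   or [build_wormnet()].
#' @param x input array. Spatial modules expect a feature map of dimension
#'   `(height, width, channels, batch)`.
#' @param training logical; `TRUE` uses batch statistics in normalization
#'   layers and caches intermediates for [wn_backward()], `FALSE` runs in
#'   frozen inference mode.
#' @return the module output (same container family as the input).
#' @export
wn_forward <- function(m, x, training = FALSE) UseMethod("wn_forward")

#' Backpropagate through a module
#'
#' Accumulates parameter gradients inside the module (retrieve them with
#' `wn_params()`) and returns the gradient with respect to the module input.
#' Must follow a `wn_forward(..., training = TRUE)` call on the same module.
#'
#' @param m a module.
#' @param dy gradient of the loss with respect to the module output.
#' @return gradient with respect to the module input.
#' @export
wn_backward <- function(m, dy) UseMethod("wn_backward")

#' Collect the parameters of a module tree
#'
#' @param m a module.
#' @param prefix name prefix used for the flattened parameter names.
#' @return named list of parameter cells; names are dot-paths such as
#'   `stem.conv.W`.
#' @export
wn_params <- function(m, prefix = "") {
  out <- list()
  for (nm in names(m$params)) {
    out[[paste0(prefix, nm)]] <- m$params[[nm]]
  }
  for (nm in names(m$children)) {
    out <- c(out, wn_params(m$children[[nm]], paste0(prefix, nm, ".")))
  }
  out
}

#' Total number of learnable scalars in a module
#' @param m a module.
#' @return integer count.
#' @export
wn_n_params <- function(m) {
  sum(vapply(wn_params(m), function(p) length(p$value), numeric(1)))
}

# sequential container
seq_module <- function(children) {
  new_module("wn_seq", children = children)
}

#' @export
wn_forward.wn_seq <- function(m, x, training = FALSE) {
  for (ch in m$children) x <- wn_forward(ch, x, training)
  x
}

#' @export
wn_backward.wn_seq <- function(m, dy) {
  for (ch in rev(m$children)) dy <- wn_backward(ch, dy)
  dy
}

# identity (used when ablation flags disable an interaction)
identity_module <- function() new_module("wn_identity")

#' @export
wn_forward.wn_identity <- function(m, x, training = FALSE) x

#' @export
wn_backward.wn_identity <- function(m, dy) dy

# ---- RNG scoping -------------------------------------------------------

# Evaluate `expr` under a temporary RNG seed, restoring global RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647L))
  expr
}

# derive a bounded child seed from a base seed and stream index
derive_seed <- function(seed, stream) {
  as.integer((as.double(seed) %% 65011 * 48271 + as.double(stream) * 16807 + 11) %% 2147483647)
}
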