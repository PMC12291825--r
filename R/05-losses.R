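# Training objective: triplet (batch-hard, cosine distance) + center +
# identity cross-entropy. Each loss has a public scalar form and an
# internal form returning the analytic gradient with respect to the
# embeddings/logits; the two are tied together by finite-difference checks
# in the test suite.

l2_normalize_cols <- function(x, eps = 1e-12) {
  sweep(x, 2, pmax(sqrt(colSums(x^2)), eps), "/")
}

#' Pairwise cosine distances between embedding columns
#'
#' @param x `D x N` matrix of embeddings (one column per sample).
#' @return `N x N` matrix of `1 - cos` distances in `[0, 2]`.
#' @export
cosine_distance <- function(x) {
  u <- l2_normalize_cols(x)
  d <- 1 - crossprod(u)
  d[d < 0] <- 0
  d
}

check_triplet_batch <- function(labels) {
  if (length(labels) < 2) stop("triplet loss needs a batch of at least 2")
  tab <- table(labels)
  if (length(tab) < 2) {
    stop("triplet loss needs at least 2 identities in the batch (no negatives)")
  }
  if (any(tab < 2)) {
    stop("triplet loss: every identity in the batch needs >= 2 samples, ",
         "violated by: ", paste(names(tab)[tab < 2], collapse = ", "))
  }
  invisible(TRUE)
}

triplet_loss_internal <- function(embeddings, labels, margin = 0.3) {
  check_triplet_batch(labels)
  B <- ncol(embeddings)
  dm <- cosine_distance(embeddings)
  same <- outer(labels, labels, "==")
  hardest_pos <- integer(B)
  hardest_neg <- integer(B)
  dp <- numeric(B)
  dn <- numeric(B)
  for (i in seq_len(B)) {
    pos <- which(same[i, ] & seq_len(B) != i)
    neg <- which(!same[i, ])
    hardest_pos[i] <- pos[which.max(dm[i, pos])]
    hardest_neg[i] <- neg[which.min(dm[i, neg])]
    dp[i] <- dm[i, hardest_pos[i]]
    dn[i] <- dm[i, hardest_neg[i]]
  }
  hinge <- dp - dn + margin
  active <- hinge > 0
  loss <- mean(pmax(hinge, 0))

  # gradient: each active anchor contributes (1/B) * (d d(i,p) - d d(i,n));
  # backprop through d(i,j) = 1 - u_i . u_j with u = x/||x||
  u <- l2_normalize_cols(embeddings)
  nrm <- pmax(sqrt(colSums(embeddings^2)), 1e-12)
  grad <- matrix(0, nrow(embeddings), B)
  add_pair_grad <- function(grad, i, j, w) {
    # contribution of w * d(i, j)
    cij <- sum(u[, i] * u[, j])
    grad[, i] <- grad[, i] - w * (u[, j] - cij * u[, i]) / nrm[i]
    grad[, j] <- grad[, j] - w * (u[, i] - cij * u[, j]) / nrm[j]
    grad
  }
  for (i in which(active)) {
    grad <- add_pair_grad(grad, i, hardest_pos[i], 1 / B)
    grad <- add_pair_grad(grad, i, hardest_neg[i], -1 / B)
  }
  list(loss = loss, grad = grad, dp = dp, dn = dn)
}

#' Batch-hard triplet loss with cosine distance
#'
#' For every anchor in the batch the hardest positive (most distant sample
#' of the same identity) and hardest negative (closest sample of a
#' different identity) are mined under cosine distance `1 - cos`, and the
#' hinge `max(0, d_p - d_n + margin)` is averaged over anchors. Intended
#' for identity-balanced PK batches (see [pk_sample()]).
#'
#' @param embeddings `D x B` matrix, one column per sample.
#' @param labels length-`B` identity labels; every identity must occur at
#'   least twice and at least two identities must be present.
#' @param margin hinge margin (default 0.3).
#' @return nonnegative scalar loss.
#' @export
triplet_loss <- function(embeddings, labels, margin = 0.3) {
  triplet_loss_internal(embeddings, labels, margin)$loss
}

#' Initialize per-identity class centers
#'
#' @param embedding_dim embedding dimension.
#' @param identities vector of identity labels to allocate centers for.
#' @param seed RNG seed for the small random initialization.
#' @return a `class_centers` object (matrix `embedding_dim x K` with one
#'   column per identity).
#' @export
init_centers <- function(embedding_dim, identities, seed = 1) {
  ids <- as.character(sort(unique(identities)))
  m <- with_seed(seed, {
    matrix(rnorm(embedding_dim * length(ids), sd = 0.01),
           embedding_dim, length(ids), dimnames = list(NULL, ids))
  })
  structure(list(centers = m), class = "class_centers")
}

center_cols <- function(centers, labels) {
  key <- as.character(labels)
  missing <- setdiff(unique(key), colnames(centers$centers))
  if (length(missing) > 0) {
    stop("no class center for identit", if (length(missing) > 1) "ies " else "y ",
         paste(missing, collapse = ", "))
  }
  match(key, colnames(centers$centers))
}

center_loss_internal <- function(embeddings, labels, centers) {
  ix <- center_cols(centers, labels)
  diff <- embeddings - centers$centers[, ix, drop = FALSE]
  list(loss = 0.5 * sum(diff^2), grad = diff)
}

#' Center loss
#'
#' One half of the summed squared Euclidean distance between each embedding
#' in the mini-batch and the center of its identity. Minimizing it pulls
#' embeddings of the same identity together (intra-class compactness).
#' Embeddings are used raw (not L2-normalized).
#'
#' @param embeddings `D x B` matrix.
#' @param labels length-`B` identity labels; each must have a center.
#' @param centers a [init_centers()] object.
#' @return nonnegative scalar loss.
#' @export
center_loss <- function(embeddings, labels, centers) {
  center_loss_internal(embeddings, labels, centers)$loss
}

#' Update class centers from a mini-batch
#'
#' Standard per-batch delta rule: for each identity present in the batch
#' the center moves toward the mean of its embeddings,
#' `c <- c - lr * sum(c - f_j) / (1 + n)`, applied to the centers only (the
#' update is not part of the network's gradient).
#'
#' @param centers a `class_centers` object.
#' @param embeddings `D x B` matrix.
#' @param labels length-`B` identity labels.
#' @param lr center learning rate (default 0.5).
#' @return the updated `class_centers` object.
#' @export
update_centers <- function(centers, embeddings, labels, lr = 0.5) {
  ix <- center_cols(centers, labels)
  for (j in unique(ix)) {
    sel <- which(ix == j)
    c_j <- centers$centers[, j]
    delta <- rowSums(c_j - embeddings[, sel, drop = FALSE]) / (1 + length(sel))
    centers$centers[, j] <- c_j - lr * delta
  }
  centers
}

identity_loss_internal <- function(logits, labels, class_ids = NULL) {
  K <- nrow(logits)
  n <- ncol(logits)
  if (length(labels) != n) stop("logits column count must match label count")
  if (is.null(class_ids)) class_ids <- seq_len(K)
  cls <- match(labels, class_ids)
  if (anyNA(cls)) {
    stop("label(s) outside the class range: ",
         paste(unique(labels[is.na(cls)]), collapse = ", "))
  }
  mx <- apply(logits, 2, max)
  z <- sweep(logits, 2, mx)
  lse <- log(colSums(exp(z)))
  logp <- sweep(z, 2, lse)
  picked <- logp[cbind(cls, seq_len(n))]
  loss <- -mean(picked)
  p <- exp(logp)
  grad <- p
  grad[cbind(cls, seq_len(n))] <- grad[cbind(cls, seq_len(n))] - 1
  list(loss = loss, grad = grad / n)
}

#' Identity (softmax cross-entropy) loss
#'
#' Mean softmax cross-entropy of the classifier logits against the ground
#' truth identities: with uniform logits over `K` classes the loss is
#' `log K`, and it approaches 0 as the correct class probability
#' approaches 1.
#'
#' @param logits `K x N` matrix of per-class scores.
#' @param labels length-`N` ground-truth identities.
#' @param class_ids identity label of each logit row (default `1:K`).
#' @return nonnegative scalar loss.
#' @export
identity_loss <- function(logits, labels, class_ids = NULL) {
  identity_loss_internal(logits, labels, class_ids)$loss
}

#' Combined training objective
#'
#' Weighted sum of the triplet, center and identity losses. The canonical
#' objective is the unweighted sum (weights `c(1, 1, 1)`); the weights are
#' exposed because the center-loss literature often downweights that term
#' (e.g. `c(1, 5e-4, 1)`).
#'
#' @param triplet,center,id the three scalar loss components.
#' @param weights numeric vector of 3 weights.
#' @return the scalar total loss.
#' @export
total_loss <- function(triplet, center, id, weights = c(1, 1, 1)) {
  stopifnot(length(weights) == 3, all(is.finite(c(triplet, center, id))))
  weights[1] * triplet + weights[2] * center + weights[3] * id
}
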