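# Independent oracles: definition-literal, loop-based recomputations used
# to cross-check the vectorized implementations.

# direct triple-loop 2-D convolution (dense), layout (H, W, C, N)
oracle_conv2d <- function(x, w, b, stride, pad) {
  d <- dim(x)
  kd <- dim(w)
  Ho <- (d[1] + 2 * pad - kd[1]) %/% stride + 1
  Wo <- (d[2] + 2 * pad - kd[2]) %/% stride + 1
  y <- array(0, c(Ho, Wo, kd[4], d[4]))
  for (n in seq_len(d[4])) for (co in seq_len(kd[4])) {
    for (wo in seq_len(Wo)) for (ho in seq_len(Ho)) {
      acc <- b[co]
      for (ci in seq_len(d[3])) for (kj in seq_len(kd[2])) for (ki in seq_len(kd[1])) {
        hi <- (ho - 1) * stride + ki - pad
        wi <- (wo - 1) * stride + kj - pad
        if (hi >= 1 && hi <= d[1] && wi >= 1 && wi <= d[2]) {
          acc <- acc + w[ki, kj, ci, co] * x[hi, wi, ci, n]
        }
      }
      y[ho, wo, co, n] <- acc
    }
  }
  y
}

# scalar-loop 1-D convolution along the channel axis with zero padding
oracle_conv1d <- function(xvec, w) {
  C <- length(xvec)
  k <- length(w)
  pad <- k %/% 2
  y <- numeric(C)
  for (i in seq_len(C)) {
    for (j in seq_len(k)) {
      src <- i + j - 1 - pad
      if (src >= 1 && src <= C) y[i] <- y[i] + w[j] * xvec[src]
    }
  }
  y
}

# exhaustive batch-hard triplet loss: loops over every anchor and every
# candidate positive/negative pair
oracle_triplet <- function(emb, labels, margin) {
  B <- ncol(emb)
  cosd <- function(a, b) {
    1 - sum(a * b) / (sqrt(sum(a^2)) * sqrt(sum(b^2)))
  }
  total <- 0
  for (i in seq_len(B)) {
    dp <- -Inf
    dn <- Inf
    for (j in seq_len(B)) {
      if (j == i) next
      dij <- cosd(emb[, i], emb[, j])
      if (labels[j] == labels[i]) dp <- max(dp, dij) else dn <- min(dn, dij)
    }
    total <- total + max(0, dp - dn + margin)
  }
  total / B
}

# scalar-loop center loss
oracle_center <- function(emb, labels, centers_mat, center_labels) {
  total <- 0
  for (j in seq_len(ncol(emb))) {
    c_j <- centers_mat[, match(as.character(labels[j]), center_labels)]
    total <- total + 0.5 * sum((emb[, j] - c_j)^2)
  }
  total
}

# scalar softmax cross-entropy, mean over samples
oracle_identity <- function(logits, labels) {
  n <- ncol(logits)
  total <- 0
  for (j in seq_len(n)) {
    p <- exp(logits[, j]) / sum(exp(logits[, j]))
    total <- total - log(p[labels[j]])
  }
  total / n
}

# definition-literal retrieval metrics: for each query, rank the gallery by
# descending similarity (ties by index), take the mean of precision at each
# relevant rank; CMC(k) counts queries whose first hit is within k
oracle_eval <- function(qv, ql, gv, gl, ranks) {
  cossim <- function(a, b) sum(a * b) / (sqrt(sum(a^2)) * sqrt(sum(b^2)))
  aps <- numeric(ncol(qv))
  first <- integer(ncol(qv))
  for (i in seq_len(ncol(qv))) {
    sims <- vapply(seq_len(ncol(gv)), function(j) cossim(qv[, i], gv[, j]),
                   numeric(1))
    ord <- order(-sims, seq_along(sims))
    rel <- gl[ord] == ql[i]
    precs <- numeric(0)
    nhit <- 0
    for (r in seq_along(rel)) {
      if (rel[r]) {
        nhit <- nhit + 1
        precs <- c(precs, nhit / r)
      }
    }
    aps[i] <- mean(precs)
    first[i] <- which(rel)[1]
  }
  list(mAP = mean(aps),
       cmc = vapply(ranks, function(k) mean(first <= k), numeric(1)))
}

# central finite differences of a scalar function at sampled positions
num_grad_at <- function(f, x, ix, h = 1e-5) {
  vapply(ix, function(i) {
    xp <- x; xp[i] <- xp[i] + h
    xm <- x; xm[i] <- xm[i] - h
    (f(xp) - f(xm)) / (2 * h)
  }, numeric(1))
}
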