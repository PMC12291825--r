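# Loss functions: closed forms, brute-force mining oracle, analytic
# gradients vs finite differences, and the geometric invariances of the
# cosine-distance triplet.

unit_at <- function(angle) c(cos(angle), sin(angle))

test_that("triplet hinge closed forms hold", {
  # two tight clusters on opposite sides: d_p = 0.5, d_n >= 1.5, hinge off
  emb <- cbind(unit_at(0), unit_at(pi / 3), unit_at(pi), unit_at(pi + pi / 3))
  labs <- c(1, 1, 2, 2)
  expect_equal(triplet_loss(emb, labs, margin = 0.3), 0)
  # all four embeddings identical: d_p = d_n = 0, loss = margin exactly
  emb2 <- matrix(1, 2, 4)
  expect_equal(triplet_loss(emb2, labs, margin = 0.3), 0.3)
  # single identity: no negative exists
  expect_error(triplet_loss(matrix(rnorm(8), 2, 4), c(1, 1, 1, 1)),
               "identities")
  expect_error(triplet_loss(matrix(rnorm(8), 2, 4), c(1, 1, 2, 3)),
               ">= 2 samples")
})

test_that("batch-hard mining equals exhaustive brute force", {
  set.seed(21)
  for (r in 1:20) {
    B <- sample(c(6, 8, 12), 1)
    ids <- rep(seq_len(B / 2), each = 2)
    emb <- matrix(rnorm(3 * B), 3, B)
    expect_equal(triplet_loss(emb, ids, 0.3), oracle_triplet(emb, ids, 0.3),
                 tolerance = 1e-12)
  }
  # a fixed 4-point, 2-identity case in 2-D
  emb <- matrix(c(1, 0, 0.8, 0.6, -1, 0.1, -0.7, -0.7), 2, 4)
  expect_equal(triplet_loss(emb, c(1, 1, 2, 2), 0.3),
               oracle_triplet(emb, c(1, 1, 2, 2), 0.3), tolerance = 1e-12)
})

test_that("triplet loss is invariant to common rescaling and rotation", {
  set.seed(22)
  emb <- matrix(rnorm(3 * 8), 3, 8)
  labs <- rep(1:2, each = 4)
  l0 <- triplet_loss(emb, labs, 0.3)
  expect_equal(triplet_loss(emb * 7.3, labs, 0.3), l0, tolerance = 1e-10)
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))   # orthogonal map
  expect_equal(triplet_loss(q %*% emb, labs, 0.3), l0, tolerance = 1e-10)
})

test_that("center loss closed forms and brute force agree", {
  centers <- init_centers(4, 1:3, seed = 2)
  # embeddings exactly at their centers
  labs <- c(1, 2, 3, 1)
  emb <- centers$centers[, as.character(labs)]
  expect_equal(center_loss(emb, labs, centers), 0)
  # one sample at Euclidean distance 2: loss = 0.5 * 4 = 2
  e1 <- centers$centers[, "2", drop = FALSE] + c(2, 0, 0, 0)
  expect_equal(center_loss(e1, 2, centers), 2)
  # random batch matches the scalar loop
  set.seed(23)
  emb5 <- matrix(rnorm(20), 4, 5)
  labs5 <- c(1, 3, 2, 1, 2)
  expect_equal(center_loss(emb5, labs5, centers),
               oracle_center(emb5, labs5, centers$centers,
                             colnames(centers$centers)),
               tolerance = 1e-12)
  expect_error(center_loss(emb5, c(1, 3, 2, 1, 9), centers), "center")
})

test_that("moving a sample toward its center strictly decreases center loss", {
  centers <- init_centers(3, 1, seed = 4)
  target <- centers$centers[, 1]
  emb <- matrix(target + c(1, 1, 1), ncol = 1)
  losses <- vapply(c(0, 0.3, 0.6, 0.9), function(a) {
    center_loss(matrix(target + (1 - a) * c(1, 1, 1), ncol = 1), 1, centers)
  }, numeric(1))
  expect_true(all(diff(losses) < 0))
})

test_that("center update rule pulls centers toward batch embeddings", {
  centers <- init_centers(2, 1:2, seed = 5)
  emb <- matrix(c(1, 1, 1, 1), 2, 2)   # two samples of identity 1 at (1,1)
  l0 <- center_loss(emb, c(1, 1), centers)
  upd <- update_centers(centers, emb, c(1, 1), lr = 0.5)
  expect_lt(center_loss(emb, c(1, 1), upd), l0)
  expect_identical(upd$centers[, "2"], centers$centers[, "2"])
})

test_that("identity loss closed forms and oracle agree", {
  # uniform logits over K classes -> log K
  for (K in c(2, 5, 10)) {
    lg <- matrix(0, K, 3)
    expect_equal(identity_loss(lg, sample(K, 3, replace = TRUE)), log(K),
                 tolerance = 1e-12)
  }
  # confident correct prediction -> loss near 0
  lg <- matrix(c(50, 0, 0), 3, 1)
  expect_lt(identity_loss(lg, 1), 1e-10)
  # hand matrix vs scalar softmax loop
  set.seed(24)
  lg3 <- matrix(rnorm(12), 3, 4)
  labs <- c(2, 1, 3, 3)
  expect_equal(identity_loss(lg3, labs), oracle_identity(lg3, labs),
               tolerance = 1e-12)
  expect_error(identity_loss(lg3, c(1, 2, 3, 4)), "class range")
})

test_that("all three losses are nonnegative on random valid batches", {
  set.seed(25)
  centers <- init_centers(5, 1:4, seed = 6)
  for (r in 1:10) {
    emb <- matrix(rnorm(5 * 8), 5, 8)
    labs <- rep(sample(1:4, 2), each = 4)
    lg <- matrix(rnorm(4 * 8), 4, 8)
    expect_gte(triplet_loss(emb, labs, 0.3), 0)
    expect_gte(center_loss(emb, labs, centers), 0)
    expect_gte(identity_loss(lg, labs, class_ids = 1:4), 0)
  }
})

test_that("analytic loss gradients match central finite differences", {
  set.seed(26)
  D <- 5; B <- 8
  emb <- matrix(rnorm(D * B), D, B)
  labs <- rep(1:2, each = 4)
  got <- wormnet:::triplet_loss_internal(emb, labs, 0.3)$grad
  ix <- sample(D * B, 12)
  want <- num_grad_at(function(e) triplet_loss(e, labs, 0.3), emb, ix)
  expect_equal(got[ix], want, tolerance = 1e-4)

  centers <- init_centers(D, 1:2, seed = 7)
  gotc <- wormnet:::center_loss_internal(emb, labs, centers)$grad
  wantc <- num_grad_at(function(e) center_loss(e, labs, centers), emb, ix)
  expect_equal(gotc[ix], wantc, tolerance = 1e-4)

  lg <- matrix(rnorm(3 * B), 3, B)
  labs3 <- sample(1:3, B, replace = TRUE)
  goti <- wormnet:::identity_loss_internal(lg, labs3)$grad
  ixl <- sample(3 * B, 10)
  wanti <- num_grad_at(function(l) identity_loss(l, labs3), lg, ixl)
  expect_equal(goti[ixl], wanti, tolerance = 1e-4)
})

test_that("total loss is the configured weighted sum", {
  expect_equal(total_loss(0.2, 0.1, 1.0), 1.3)
  expect_equal(total_loss(0, 0, 0), 0)
  expect_equal(total_loss(0.2, 10, 0.5, weights = c(1, 5e-4, 1)), 0.705)
  expect_error(total_loss(NaN, 0, 0), "finite")
})
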