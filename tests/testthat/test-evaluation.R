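# Retrieval evaluation: similarity arithmetic, mAP/CMC against the
# definition-literal oracle, ranking invariances, visualization output.

test_that("cosine similarity matches the scalar dot/norm loop", {
  q <- matrix(c(1, 0, 0, 1, 1, 1), 2, 3)
  g <- matrix(c(2, 0, -1, 1), 2, 2)
  s <- similarity_matrix(q, g)
  expect_equal(dim(s), c(3, 2))
  for (i in 1:3) for (j in 1:2) {
    expect_equal(s[i, j],
                 sum(q[, i] * g[, j]) / (sqrt(sum(q[, i]^2)) * sqrt(sum(g[, j]^2))),
                 tolerance = 1e-12)
  }
  expect_equal(s[1, 1], 1)   # identical direction
  expect_equal(s[2, 1], 0)   # orthogonal
  expect_true(all(s >= -1 - 1e-12 & s <= 1 + 1e-12))
})

test_that("zero-norm embeddings are rejected by name", {
  q <- embedding_set(matrix(c(1, 0, 0, 0), 2, 2), c(1, 2), "query",
                     source_id = c("ok.png", "broken.png"))
  g <- embedding_set(matrix(c(1, 1), 2, 1), 1, "gallery")
  expect_error(similarity_matrix(q, g), "broken.png")
})

test_that("single-query closed forms hold", {
  g <- embedding_set(cbind(c(1, 0), c(0, 1)), c(7, 8), "gallery")
  q <- embedding_set(cbind(c(1, 0)), 7, "query")
  r <- evaluate_reid(q, g, ranks = 1:2)
  expect_equal(r$mAP, 1)
  expect_equal(unname(r$cmc[["rank1"]]), 1)
  # only positive ranked second of two: AP = 0.5, CMC(1) = 0, CMC(2) = 1
  q2 <- embedding_set(cbind(c(0.9, 0.45)), 8, "query")
  r2 <- evaluate_reid(q2, g, ranks = 1:2)
  expect_equal(r2$mAP, 0.5)
  expect_equal(unname(r2$cmc), c(0, 1))
})

test_that("mAP and CMC equal the brute-force recomputation on random instances", {
  set.seed(31)
  for (r in 1:100) {
    ng <- sample(5:30, 1)
    nq <- sample(2:5, 1)
    nid <- sample(2:4, 1)
    D <- sample(3:6, 1)
    gl <- c(seq_len(nid), sample(nid, ng - nid, replace = TRUE))
    ql <- sample(nid, nq, replace = TRUE)
    gv <- matrix(rnorm(D * ng), D, ng)
    qv <- matrix(rnorm(D * nq), D, nq)
    ranks <- c(1, 5, 10)
    got <- evaluate_reid(embedding_set(qv, ql, "query"),
                         embedding_set(gv, gl, "gallery"), ranks)
    want <- oracle_eval(qv, ql, gv, gl, pmin(ranks, ng))
    expect_equal(got$mAP, want$mAP, tolerance = 1e-9)
    expect_equal(unname(got$cmc), want$cmc, tolerance = 1e-9)
  }
})

test_that("gallery permutation leaves the metrics unchanged", {
  set.seed(32)
  gv <- matrix(rnorm(4 * 12), 4, 12)
  gl <- rep(1:3, 4)
  qv <- matrix(rnorm(4 * 5), 4, 5)
  ql <- sample(1:3, 5, replace = TRUE)
  r0 <- evaluate_reid(embedding_set(qv, ql, "query"),
                      embedding_set(gv, gl, "gallery"))
  perm <- sample(12)
  r1 <- evaluate_reid(embedding_set(qv, ql, "query"),
                      embedding_set(gv[, perm], gl[perm], "gallery"))
  expect_equal(r1$mAP, r0$mAP, tolerance = 1e-12)
  expect_equal(r1$cmc, r0$cmc, tolerance = 1e-12)
})

test_that("a pure distractor never improves any query's AP", {
  set.seed(33)
  gv <- matrix(rnorm(4 * 10), 4, 10)
  gl <- rep(1:2, 5)
  qv <- matrix(rnorm(4 * 6), 4, 6)
  ql <- rep(1:2, 3)
  base <- evaluate_reid(embedding_set(qv, ql, "query"),
                        embedding_set(gv, gl, "gallery"))
  with_distractor <- evaluate_reid(
    embedding_set(qv, ql, "query"),
    embedding_set(cbind(gv, rnorm(4)), c(gl, 99), "gallery"))
  expect_true(all(with_distractor$ap <= base$ap + 1e-12))
})

test_that("CMC is non-decreasing and reaches 1 at the gallery size", {
  set.seed(34)
  gv <- matrix(rnorm(3 * 15), 3, 15)
  gl <- rep(1:3, 5)
  qv <- matrix(rnorm(3 * 6), 3, 6)
  ql <- rep(1:3, 2)
  r <- evaluate_reid(embedding_set(qv, ql, "query"),
                     embedding_set(gv, gl, "gallery"), ranks = 1:15)
  expect_true(all(diff(r$cmc) >= 0))
  expect_equal(unname(r$cmc[["rank15"]]), 1)
})

test_that("queries without a gallery identity are excluded with a warning", {
  g <- embedding_set(cbind(c(1, 0), c(0, 1)), c(1, 1), "gallery")
  q <- embedding_set(cbind(c(1, 0), c(0, 1)), c(1, 42), "query",
                     source_id = c("a.png", "lost.png"))
  expect_warning(r <- evaluate_reid(q, g), "lost.png")
  expect_equal(r$n_query, 1)
})

test_that("embedding cache round-trips through CSV", {
  set.seed(35)
  es <- embedding_set(matrix(rnorm(12), 3, 4), c(1, 1, 2, 2), "gallery",
                      source_id = paste0("img", 1:4, ".png"))
  f <- tempfile(fileext = ".csv")
  write_embeddings(es, f)
  back <- read_embeddings(f, "gallery")
  expect_equal(back$vectors, es$vectors, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(back$labels, es$labels)
  expect_equal(back$source_id, es$source_id)
})

test_that("top-k panels are written with the expected geometry", {
  set.seed(36)
  imgs <- lapply(1:4, function(i) array(runif(20 * 20 * 3), c(20, 20, 3)))
  f <- tempfile(fileext = ".png")
  visualize_topk(imgs[[1]], imgs[-1], correct = c(TRUE, FALSE, TRUE), k = 3,
                 file = f, border = 2)
  expect_true(file.exists(f))
  img <- EBImage::readImage(f)
  expect_equal(dim(img)[2], 20)                 # height
  expect_equal(dim(img)[1], 4 * 20 + 3 * 6)     # 4 panels + 3 gaps
  # k = 0 draws the query alone
  f0 <- tempfile(fileext = ".png")
  visualize_topk(imgs[[1]], list(), logical(0), k = 0, file = f0)
  expect_equal(dim(EBImage::readImage(f0))[1], 20)
  expect_error(visualize_topk(imgs[[1]], imgs[-1], c(TRUE, TRUE, TRUE), k = 9,
                              file = f), "exceeds")
})
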