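# Synthetic generator: determinism, geometry, split bookkeeping, and the
# difficulty knob's effect on raw-pixel separability.

test_that("rendering is seed-deterministic and identity parameters are fixed", {
  ids <- worm_identities(3, difficulty = 0.4, seed = 9)
  r1 <- render_worm(ids[2, ], pose_seed = 5)
  r2 <- render_worm(ids[2, ], pose_seed = 5)
  expect_identical(r1$image, r2$image)
  r3 <- render_worm(ids[2, ], pose_seed = 6)
  expect_false(identical(r1$image, r3$image))
  expect_equal(r1$identity, r3$identity)
  expect_equal(dim(r1$image), c(224, 224, 3))
  expect_true(all(r1$image >= 0 & r1$image <= 1))
  # identity tables are reproducible
  expect_identical(worm_identities(3, 0.4, seed = 9), ids)
})

test_that("pose varies while identity parameters stay put across renderings", {
  ids <- worm_identities(2, difficulty = 0, seed = 4)
  poses <- lapply(1:4, function(s) render_worm(ids[1, ], s)$pose)
  angles <- vapply(poses, function(p) p$theta0, numeric(1))
  expect_gt(stats::sd(angles), 0)   # orientations differ between renders
  expect_true(all(angles >= 0 & angles < 2 * pi))
})

test_that("dataset layout, manifest and split invariants hold", {
  ds <- tiny_dataset()
  m <- ds$manifest
  # 2 train ids x 8 + 2 test ids x (6 gallery + 2 query)
  expect_equal(sum(m$split == "train"), 16)
  expect_equal(sum(m$split == "gallery"), 12)
  expect_equal(sum(m$split == "query"), 4)
  train_ids <- unique(m$identity[m$split == "train"])
  test_ids <- unique(m$identity[m$split != "train"])
  expect_length(intersect(train_ids, test_ids), 0)
  expect_true(all(unique(m$identity[m$split == "query"]) %in%
                    unique(m$identity[m$split == "gallery"])))
  expect_true(all(file.exists(file.path(ds$dir, m$file))))
  # images decode to exactly 224 x 224 x 3
  x <- load_images(file.path(ds$dir, m$file[1]))
  expect_equal(dim(x), c(224, 224, 3, 1))
  # layout is re-loadable from disk, with and without the manifest
  back <- load_reid_dataset(ds$dir)
  expect_equal(sort(back$manifest$file), sort(m$file))
  unlink(file.path(ds$dir, "manifest.csv"))
  scanned <- load_reid_dataset(ds$dir)
  expect_equal(sort(scanned$manifest$file), sort(m$file))
  expect_equal(sum(scanned$manifest$split == "query"), 4)
  utils::write.csv(m, file.path(ds$dir, "manifest.csv"), row.names = FALSE)
})

test_that("degenerate split requests are rejected", {
  expect_error(generate_dataset(images_per_id = 1), ">= 2")
  expect_error(generate_dataset(images_per_id = 4, queries_per_id = 4),
               "at least one gallery image")
})

test_that("identical seeds reproduce identical manifests", {
  d1 <- file.path(tempdir(), "wormnet-det-a")
  d2 <- file.path(tempdir(), "wormnet-det-b")
  ds1 <- generate_dataset(n_train_ids = 2, n_test_ids = 2, images_per_id = 3,
                          queries_per_id = 1, seed = 5, dir = d1, size = 64)
  ds2 <- generate_dataset(n_train_ids = 2, n_test_ids = 2, images_per_id = 3,
                          queries_per_id = 1, seed = 5, dir = d2, size = 64)
  expect_identical(ds1$manifest, ds2$manifest)
  expect_identical(load_images(file.path(d1, ds1$manifest$file[1])),
                   load_images(file.path(d2, ds2$manifest$file[1])))
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("raising difficulty lowers raw-pixel nearest-neighbor separability", {
  pixel_rank1 <- function(difficulty, seed, n_ids = 6, per_id = 5) {
    ids <- worm_identities(n_ids, difficulty, seed)
    embs <- matrix(0, 24 * 24 * 3, n_ids * per_id)
    labs <- integer(0)
    k <- 0
    for (i in seq_len(n_ids)) for (j in seq_len(per_id)) {
      img <- render_worm(ids[i, ], pose_seed = j * 131 + seed)$image
      small <- EBImage::resize(
        EBImage::Image(aperm(img, c(2, 1, 3)), colormode = "Color"), 24, 24)
      k <- k + 1
      embs[, k] <- as.vector(small)
      labs <- c(labs, i)
    }
    v <- embs - rowMeans(embs)
    sim <- crossprod(sweep(v, 2, pmax(sqrt(colSums(v^2)), 1e-9), "/"))
    diag(sim) <- -Inf
    mean(labs[apply(sim, 1, which.max)] == labs)
  }
  means <- vapply(c(0, 0.5, 1), function(d) {
    mean(vapply(1:5, function(s) pixel_rank1(d, s), numeric(1)))
  }, numeric(1))
  expect_true(all(diff(means) < 0))
  # and at zero difficulty the classifier clearly beats chance (~1/6)
  expect_gt(means[1], 1 / 6)
})
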