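# Synthetic worm-image generator.
#
# Emulates the structure of a top-down larva re-identification dataset:
# one elongated, arbitrarily oriented and bent worm per image, rendered at
# its natural crop size over background clutter, then padded with a
# uniform color to 224x224. Identity is carried by body geometry (length,
# width), coloring and a segment-band marking pattern that are fixed
# across all renderings of the same identity; pose (orientation, bend,
# placement) and clutter vary per image.

#' Sample a set of worm identities
#'
#' Each identity is a fixed parameter bundle (body length and width in
#' pixels, curvature range in radians, hue/saturation/value, band pattern
#' and a marking seed). A difficulty knob controls inter-identity
#' separation: at 0 the identity parameters are spread maximally (evenly
#' spaced hues, wide size range), at 1 they collapse onto a common
#' greenish-white larva with small jitter, so identities become nearly
#' indistinguishable from parameters alone.
#'
#' @param n number of identities.
#' @param difficulty inter-identity similarity in `[0, 1]`.
#' @param seed RNG seed.
#' @return data frame with one row per identity.
#' @export
worm_identities <- function(n, difficulty = 0.5, seed = 1) {
  stopifnot(n >= 1, difficulty >= 0, difficulty <= 1)
  d <- difficulty
  with_seed(seed, {
    spread <- function(center, halfwidth, common) {
      # evenly spaced quantiles (shuffled), compressed toward `common` as
      # difficulty rises; small jitter keeps identities off a lattice
      q <- (sample(n) - 0.5) / n
      base <- center + (2 * q - 1) * halfwidth
      (1 - d) * base + d * common + rnorm(n, sd = 0.02 * halfwidth + 1e-9)
    }
    data.frame(
      id = seq_len(n),
      body_length = pmin(pmax(spread(95, 35, 95), 45), 140),
      body_width = pmin(pmax(spread(13, 5, 12), 6), 20),
      curvature = pmin(pmax(spread(1.6, 1.1, 1.8), 0.2), 3),
      hue = ((sample(n) - 0.5) / n * (1 - d) + d * 0.31 +
               rnorm(n, sd = 0.01)) %% 1,
      sat = pmin(pmax(spread(0.55, 0.25, 0.18), 0.05), 0.9),
      val = pmin(pmax(spread(0.7, 0.2, 0.82), 0.35), 0.95),
      band_freq = pmax(1, round(spread(5.5, 3.5, 5))),
      band_amp = pmin(pmax(spread(0.3, 0.2, 0.12), 0.02), 0.6),
      marking_seed = sample.int(1e6, n)
    )
  })
}

#' Render one worm image
#'
#' Draws a smooth tapered tube along a random low-order curve with the
#' identity's width/length/coloring, at a per-sample random orientation in
#' `[0, 2pi)` and bend, over additive background clutter (random blobs and
#' streaks). The render is cropped to the worm's tight bounding box and
#' padded with a uniform color to `size x size`. Fully seed-deterministic:
#' the same identity and pose seed reproduce the image bit for bit.
#'
#' @param identity one row of [worm_identities()].
#' @param pose_seed integer; varies pose, clutter and placement.
#' @param size output side in pixels (default 224).
#' @param pad_color uniform padding color in `[0, 1]` (default mid-gray).
#' @return list with `image` (`size x size x 3` array in `[0, 1]`),
#'   `identity` (the id), and `pose` (orientation/bend parameters).
#' @export
render_worm <- function(identity, pose_seed, size = 224, pad_color = 0.5) {
  stopifnot(nrow(identity) == 1)
  seed <- derive_seed(identity$marking_seed, pose_seed)
  with_seed(seed, {
    # ---- spine: integrate a random curvature profile -------------------
    npts <- 80
    theta0 <- runif(1, 0, 2 * pi)
    c2 <- runif(1, -identity$curvature, identity$curvature)
    c3 <- runif(1, -identity$curvature, identity$curvature)
    t <- seq(0, 1, length.out = npts)
    phi <- theta0 + c2 * (t - 0.5) + c3 * (t - 0.5)^2
    step <- identity$body_length / (npts - 1)
    px <- cumsum(c(0, cos(phi[-1]) * step))
    py <- cumsum(c(0, sin(phi[-1]) * step))
    halfw <- 0.5 * identity$body_width * (0.2 + 0.8 * sin(pi * t)^0.5)

    # ---- natural-size canvas around the worm ---------------------------
    margin <- max(halfw) + 6
    px <- px - min(px) + margin
    py <- py - min(py) + margin
    W <- min(ceiling(max(px) + margin), size)
    H <- min(ceiling(max(py) + margin), size)

    gx <- matrix(rep(seq_len(W), each = H), H, W)   # columns = x
    gy <- matrix(rep(seq_len(H), W), H, W)          # rows = y
    dmin <- matrix(Inf, H, W)
    tnear <- matrix(1L, H, W)
    for (j in seq_len(npts)) {
      dj <- (gx - px[j])^2 + (gy - py[j])^2
      upd <- dj < dmin
      dmin[upd] <- dj[upd]
      tnear[upd] <- j
    }
    dmin <- sqrt(dmin)
    wnear <- matrix(halfw[tnear], H, W)
    alpha <- pmin(pmax((wnear - dmin) / 1.2, 0), 1)  # soft-edged tube mask

    # ---- identity coloring with segment bands and speckle --------------
    base_rgb <- grDevices::hsv(identity$hue, identity$sat, 1)
    base <- as.vector(grDevices::col2rgb(base_rgb)) / 255
    tmap <- matrix(t[tnear], H, W)
    band <- 1 + identity$band_amp *
      sin(2 * pi * identity$band_freq * tmap +
            2 * pi * (identity$marking_seed %% 997) / 997)
    shade <- identity$val * band *
      (1 - 0.35 * (dmin / pmax(wnear, 1e-6))^2)     # cylindrical shading
    speckle <- matrix(rnorm(H * W, sd = 0.03), H, W)
    worm <- array(0, c(H, W, 3))
    for (ch in 1:3) worm[, , ch] <- pmin(pmax(base[ch] * shade + speckle, 0), 1)

    # ---- background clutter: blobs and streaks -------------------------
    bg_base <- runif(1, 0.35, 0.65)
    bg <- array(bg_base + rnorm(1, sd = 0.03), c(H, W, 3))
    for (b in seq_len(6)) {
      cx <- runif(1, 1, W); cy <- runif(1, 1, H)
      rx <- runif(1, 4, W / 3); ry <- runif(1, 4, H / 3)
      ang <- runif(1, 0, pi)
      xr <- (gx - cx) * cos(ang) + (gy - cy) * sin(ang)
      yr <- -(gx - cx) * sin(ang) + (gy - cy) * cos(ang)
      blob <- exp(-((xr / rx)^2 + (yr / ry)^2) * 2)
      col <- runif(3, 0.2, 0.8)
      for (ch in 1:3) bg[, , ch] <- bg[, , ch] + 0.4 * blob * (col[ch] - bg_base)
    }
    bg <- pmin(pmax(bg + array(rnorm(H * W * 3, sd = 0.02), c(H, W, 3)), 0), 1)

    crop <- bg
    for (ch in 1:3) {
      crop[, , ch] <- bg[, , ch] * (1 - alpha) + worm[, , ch] * alpha
    }

    # ---- pad with a uniform color to size x size (symmetric) -----------
    out <- array(pad_color, c(size, size, 3))
    oy <- (size - H) %/% 2 + 1L
    ox <- (size - W) %/% 2 + 1L
    out[oy + seq_len(H) - 1L, ox + seq_len(W) - 1L, ] <- crop
    list(image = out, identity = identity$id,
         pose = list(theta0 = theta0, c2 = c2, c3 = c3,
                     offset = c(oy, ox), crop_size = c(H, W)))
  })
}

#' Generate a Market1501-style synthetic dataset
#'
#' Renders identity-labelled worm images and writes them into the standard
#' re-identification directory layout: `bounding_box_train/` (training
#' identities), `bounding_box_test/` (gallery) and `query/`, with file
#' names `<id>_<index>.png`, plus a `manifest.csv` listing every sample.
#' Training and test identity sets are disjoint; the query set is a random
#' per-identity subset of the test images (removed from the gallery, as in
#' the standard protocol).
#'
#' @param n_train_ids,n_test_ids identity counts for the two splits
#'   (defaults 20/10, a desk-scale mirror of a 130/90 identity corpus).
#' @param images_per_id renderings per identity (>= 2, default 20).
#' @param queries_per_id query images drawn per test identity (default 5;
#'   must leave at least one gallery image).
#' @param difficulty identity-separation knob, see [worm_identities()].
#' @param seed RNG seed; fixed seeds reproduce the dataset bit for bit.
#' @param dir output directory.
#' @param size,pad_color image geometry, see [render_worm()].
#' @return a `reid_dataset`: list with `dir`, `manifest` (data frame with
#'   columns `file`, `identity`, `split`, `pose_seed`) and `identities`.
#' @export
generate_dataset <- function(n_train_ids = 20, n_test_ids = 10,
                             images_per_id = 20, queries_per_id = 5,
                             difficulty = 0.5, seed = 1,
                             dir = tempfile("wormset"),
                             size = 224, pad_color = 0.5) {
  if (images_per_id < 2) {
    stop("images_per_id must be >= 2 (retrieval needs at least one gallery match)")
  }
  if (queries_per_id >= images_per_id) {
    stop("queries_per_id must leave at least one gallery image per identity")
  }
  n <- n_train_ids + n_test_ids
  ids <- worm_identities(n, difficulty, seed)
  train_ids <- with_seed(derive_seed(seed, 1L), sample(ids$id, n_train_ids))
  test_ids <- setdiff(ids$id, train_ids)

  subdirs <- c("bounding_box_train", "bounding_box_test", "query")
  for (s in subdirs) dir.create(file.path(dir, s), recursive = TRUE,
                                showWarnings = FALSE)
  rows <- list()
  for (i in seq_len(n)) {
    id <- ids$id[i]
    is_train <- id %in% train_ids
    q_ix <- if (is_train) integer(0) else {
      with_seed(derive_seed(seed, 1000L + id),
                sample.int(images_per_id, queries_per_id))
    }
    for (j in seq_len(images_per_id)) {
      pose_seed <- derive_seed(seed, id * 10000L + j)
      split <- if (is_train) "train" else if (j %in% q_ix) "query" else "gallery"
      sub <- c(train = "bounding_box_train", gallery = "bounding_box_test",
               query = "query")[[split]]
      fn <- file.path(sub, sprintf("%04d_%03d.png", id, j))
      r <- render_worm(ids[i, ], pose_seed, size, pad_color)
      EBImage::writeImage(
        EBImage::Image(aperm(r$image, c(2, 1, 3)), colormode = "Color"),
        file.path(dir, fn))
      rows[[length(rows) + 1]] <- data.frame(
        file = fn, identity = id, split = split, pose_seed = pose_seed)
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  structure(list(dir = dir, manifest = manifest, identities = ids),
            class = "reid_dataset")
}

#' Load a dataset in the Market1501-style layout
#'
#' Reads `manifest.csv` when present; otherwise scans the three standard
#' subdirectories and parses `<id>_<index>.<ext>` file names.
#'
#' @param dir dataset directory.
#' @return a `reid_dataset`.
#' @export
load_reid_dataset <- function(dir) {
  mf <- file.path(dir, "manifest.csv")
  if (file.exists(mf)) {
    manifest <- utils::read.csv(mf)
  } else {
    subs <- c(train = "bounding_box_train", gallery = "bounding_box_test",
              query = "query")
    rows <- list()
    for (split in names(subs)) {
      d <- file.path(dir, subs[[split]])
      if (!dir.exists(d)) next
      files <- list.files(d, pattern = "\\.(png|jpg|jpeg)$", ignore.case = TRUE)
      if (length(files) == 0) next
      id <- as.integer(sub("_.*$", "", files))
      rows[[split]] <- data.frame(file = file.path(subs[[split]], files),
                                  identity = id, split = split,
                                  pose_seed = NA_integer_)
    }
    if (length(rows) == 0) stop("no dataset found under ", dir)
    manifest <- do.call(rbind, rows)
    rownames(manifest) <- NULL
  }
  structure(list(dir = dir, manifest = manifest, identities = NULL),
            class = "reid_dataset")
}

#' @export
print.reid_dataset <- function(x, ...) {
  tab <- table(x$manifest$split)
  cat("reid_dataset at ", x$dir, "\n", sep = "")
  for (s in names(tab)) {
    ids <- length(unique(x$manifest$identity[x$manifest$split == s]))
    cat(sprintf("  %-8s %4d images, %3d identities\n", s, tab[[s]], ids))
  }
  invisible(x)
}

#' Load images as a feature-map batch
#'
#' @param paths PNG/JPEG file paths.
#' @param size optional target side; images are bilinearly resized.
#' @return `(H, W, 3, N)` array with values in `[0, 1]`.
#' @export
load_images <- function(paths, size = NULL) {
  imgs <- lapply(paths, function(p) {
    img <- EBImage::readImage(p)
    if (length(dim(img)) == 2) img <- EBImage::Image(
      array(rep(img, 3), c(dim(img), 3)), colormode = "Color")
    if (dim(img)[3] > 3) img <- img[, , 1:3]
    if (!is.null(size) && (dim(img)[1] != size || dim(img)[2] != size)) {
      img <- EBImage::resize(img, w = size, h = size)
    }
    aperm(as.array(img), c(2, 1, 3))  # -> (H, W, C)
  })
  d <- dim(imgs[[1]])
  out <- array(0, c(d[1], d[2], 3, length(imgs)))
  for (i in seq_along(imgs)) out[, , , i] <- imgs[[i]]
  out
}

#' Per-channel normalization statistics
#'
#' @param x `(H, W, 3, N)` image batch, typically the training split.
#' @return list with `mean` and `sd` (length-3 each).
#' @export
image_stats <- function(x) {
  d <- dim(x)
  m <- matrix(.colMeans(x, d[1] * d[2], d[3] * d[4]), d[3], d[4])
  m2 <- matrix(.colMeans(x * x, d[1] * d[2], d[3] * d[4]), d[3], d[4])
  mu <- rowMeans(m)
  sd <- sqrt(pmax(rowMeans(m2) - mu^2, 1e-8))
  list(mean = mu, sd = sd)
}

#' Standardize an image batch with dataset statistics
#'
#' @param x `(H, W, 3, N)` batch in `[0, 1]`.
#' @param stats output of [image_stats()] computed on the training split.
#' @return standardized batch.
#' @export
normalize_images <- function(x, stats) {
  d <- dim(x)
  hw <- d[1] * d[2]
  y <- (x - bcast_cn(matrix(stats$mean, d[3], d[4]), hw)) /
    bcast_cn(matrix(stats$sd, d[3], d[4]), hw)
  dim(y) <- d
  y
}
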