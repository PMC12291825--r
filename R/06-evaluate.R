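#' Construct an embedding set
#'
#' Container tying embeddings to identity labels for retrieval evaluation.
#'
#' @param vectors `D x N` matrix, one column per image.
#' @param labels length-`N` identity labels.
#' @param role `"query"` or `"gallery"`.
#' @param source_id optional length-`N` image identifiers (file names);
#'   defaults to `role_1 ... role_N`.
#' @return an object of class `embedding_set`.
#' @export
embedding_set <- function(vectors, labels, role = c("gallery", "query"),
                          source_id = NULL) {
  role <- match.arg(role)
  vectors <- as.matrix(vectors)
  if (ncol(vectors) != length(labels)) {
    stop("vectors must have one column per label")
  }
  if (is.null(source_id)) {
    source_id <- paste0(role, "_", seq_along(labels))
  }
  structure(list(vectors = vectors, labels = labels, role = role,
                 source_id = source_id),
            class = "embedding_set")
}

#' @export
print.embedding_set <- function(x, ...) {
  cat(sprintf("embedding_set: %d %s embeddings of dim %d, %d identities\n",
              ncol(x$vectors), x$role, nrow(x$vectors),
              length(unique(x$labels))))
  invisible(x)
}

#' Cosine similarity between query and gallery embeddings
#'
#' @param queries,gallery [embedding_set()] objects (or bare matrices) with
#'   matching embedding dimension; no embedding may have zero norm.
#' @return `n_query x n_gallery` matrix of cosine similarities in
#'   `[-1, 1]`.
#' @export
similarity_matrix <- function(queries, gallery) {
  qv <- if (inherits(queries, "embedding_set")) queries$vectors else as.matrix(queries)
  gv <- if (inherits(gallery, "embedding_set")) gallery$vectors else as.matrix(gallery)
  if (nrow(qv) != nrow(gv)) stop("embedding dimensions differ")
  check_norms <- function(v, set, what) {
    bad <- which(sqrt(colSums(v^2)) < 1e-12)
    if (length(bad) > 0) {
      ids <- if (inherits(set, "embedding_set")) set$source_id[bad] else bad
      stop("zero-norm ", what, " embedding(s): ",
           paste(ids, collapse = ", "))
    }
  }
  check_norms(qv, queries, "query")
  check_norms(gv, gallery, "gallery")
  crossprod(l2_normalize_cols(qv), l2_normalize_cols(gv))
}

average_precision <- function(rel) {
  hits <- which(rel)
  if (length(hits) == 0) return(NA_real_)
  mean(cumsum(rel)[hits] / hits)
}

#' Retrieval evaluation: mAP and CMC
#'
#' For each query the gallery is ranked by descending cosine similarity
#' (ties broken by ascending gallery index, so results are deterministic).
#' Average precision is the exact (non-interpolated) mean of the precision
#' values at each rank where a correct match occurs; mAP averages it over
#' queries. CMC at rank k is the fraction of queries whose first correct
#' match appears within the top k. Queries whose identity is absent from
#' the gallery are excluded with a warning.
#'
#' @param queries,gallery [embedding_set()] objects.
#' @param ranks CMC ranks to report (default 1, 5, 10; ranks beyond the
#'   gallery size are clamped).
#' @return an object of class `eval_report`: list with `mAP`, `cmc` (named
#'   vector), `per_query_rankings` (list of gallery index orderings),
#'   `ap` (per-query APs), `n_query`, `n_gallery`, `excluded`.
#' @export
evaluate_reid <- function(queries, gallery, ranks = c(1, 5, 10)) {
  if (ncol(queries$vectors) == 0 || ncol(gallery$vectors) == 0) {
    stop("queries and gallery must be nonempty")
  }
  keep <- queries$labels %in% gallery$labels
  excluded <- queries$source_id[!keep]
  if (length(excluded) > 0) {
    warning(length(excluded), " quer", if (length(excluded) > 1) "ies" else "y",
            " with no gallery match excluded: ",
            paste(utils::head(excluded, 5), collapse = ", "))
  }
  if (!any(keep)) stop("no query identity is present in the gallery")
  sim <- similarity_matrix(queries, gallery)
  ranks <- pmin(as.integer(ranks), ncol(gallery$vectors))
  nq <- sum(keep)
  ap <- numeric(nq)
  first_hit <- integer(nq)
  rankings <- vector("list", nq)
  qi <- which(keep)
  for (t in seq_len(nq)) {
    i <- qi[t]
    ord <- order(-sim[i, ], seq_len(ncol(sim)))   # stable tie-break by index
    rel <- gallery$labels[ord] == queries$labels[i]
    ap[t] <- average_precision(rel)
    first_hit[t] <- which(rel)[1]
    rankings[[t]] <- ord
  }
  cmc <- vapply(ranks, function(k) mean(first_hit <= k), numeric(1))
  names(cmc) <- paste0("rank", ranks)
  structure(list(
    mAP = mean(ap), cmc = cmc, ap = ap,
    per_query_rankings = rankings,
    query_ids = queries$source_id[keep],
    n_query = nq, n_gallery = ncol(gallery$vectors),
    excluded = excluded
  ), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("Retrieval evaluation: %d queries vs %d gallery images\n",
              x$n_query, x$n_gallery))
  cat(sprintf("  mAP: %.4f\n", x$mAP))
  for (nm in names(x$cmc)) cat(sprintf("  CMC %s: %.4f\n", nm, x$cmc[[nm]]))
  if (length(x$excluded) > 0) {
    cat(sprintf("  (%d queries excluded: identity absent from gallery)\n",
                length(x$excluded)))
  }
  invisible(x)
}

#' Write an evaluation report as JSON
#'
#' @param report an `eval_report`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(report, path) {
  jsonlite::write_json(
    list(mAP = report$mAP, cmc = as.list(report$cmc),
         n_query = report$n_query, n_gallery = report$n_gallery,
         excluded = report$excluded),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Top-k retrieval panel
#'
#' Renders a query image next to its top-k retrieved gallery images as a
#' single horizontal strip, frame-coded in the usual way: the query frame
#' is purple, correct matches green, incorrect matches red. Written as a
#' PNG.
#'
#' @param query_image `(H, W, 3)` array in `[0, 1]`.
#' @param gallery_images list of `(H, W, 3)` arrays, already in ranked
#'   order.
#' @param correct logical vector, one flag per gallery image.
#' @param k number of retrieved panels to draw (`k <= length(gallery_images)`;
#'   `k = 0` draws the query alone).
#' @param file output PNG path.
#' @param border border thickness in pixels.
#' @return `file`, invisibly.
#' @export
visualize_topk <- function(query_image, gallery_images, correct, k,
                           file, border = 4) {
  if (k > length(gallery_images)) stop("k exceeds the number of gallery images")
  frame <- function(img, col) {
    d <- dim(img)
    b <- border
    for (ch in 1:3) {
      img[seq_len(b), , ch] <- col[ch]
      img[d[1] - seq_len(b) + 1, , ch] <- col[ch]
      img[, seq_len(b), ch] <- col[ch]
      img[, d[2] - seq_len(b) + 1, ch] <- col[ch]
    }
    img
  }
  purple <- c(0.6, 0.2, 0.8); green <- c(0, 0.8, 0); red <- c(0.9, 0, 0)
  panels <- list(frame(query_image, purple))
  for (j in seq_len(k)) {
    panels[[j + 1]] <- frame(gallery_images[[j]],
                             if (correct[j]) green else red)
  }
  gap <- 6
  h <- dim(query_image)[1]
  w <- dim(query_image)[2]
  strip <- array(1, c(h, (w + gap) * length(panels) - gap, 3))
  for (j in seq_along(panels)) {
    x0 <- (j - 1) * (w + gap)
    strip[, x0 + seq_len(w), ] <- panels[[j]]
  }
  # EBImage uses (x, y, channel) order
  EBImage::writeImage(EBImage::Image(aperm(strip, c(2, 1, 3)),
                                     colormode = "Color"), file)
  invisible(file)
}
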