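# Cross-modality label transfer: a joint PCA embedding of reference and
# query expression on shared genes, a soft-cluster centroid-matching batch
# alignment, k-NN label voting, and concordance/enrichment summaries.

#' Fit a batch-aligned joint embedding
#'
#' Concatenates reference and query on their shared genes (both are
#' expected to be normalised log1p upstream), z-scales each gene over the
#' union, and computes a PCA. Batch alignment then iterates a soft k-means
#' in PC space: cells get Gaussian-kernel responsibilities to the cluster
#' centres, per-batch per-cluster soft centroids are compared to the global
#' soft centroid, and each cell is shifted by its responsibility-weighted
#' batch offsets. PC signs are canonicalised (largest-magnitude loading
#' positive) so the embedding is reproducible across gene and cell order.
#'
#' @param ref,query Matrices of normalised log1p expression (cells x
#'   genes) with gene column names.
#' @param n_pcs Number of principal components (default 30).
#' @param n_align_iters Alignment iterations; 0 gives plain joint PCA.
#' @param n_clusters Soft-cluster count; defaults to
#'   `max(10, length(unique(ref_labels)))` when labels are supplied, 10
#'   otherwise.
#' @param ref_labels Optional reference labels (only used to size the
#'   cluster count).
#' @param min_shared Minimum number of shared genes (default 50).
#' @param seed Integer seed.
#' @return An `embedding_model` with the shared gene list, per-gene
#'   centre/scale, rotation, and the aligned `ref_embedding` /
#'   `query_embedding`.
#' @export
fit_joint_embedding <- function(ref, query, n_pcs = 30, n_align_iters = 10,
                                n_clusters = NULL, ref_labels = NULL,
                                min_shared = 50, seed = 1L) {
  ref <- as.matrix(ref); query <- as.matrix(query)
  shared <- intersect(colnames(ref), colnames(query))
  if (length(shared) < min_shared) {
    zm_stop(sprintf("only %d shared genes (need >= %d)", length(shared), min_shared),
      "zonemap_integration_error")
  }
  x <- rbind(ref[, shared, drop = FALSE], query[, shared, drop = FALSE])
  center <- colMeans(x)
  scale_ <- apply(x, 2, stats::sd)
  scale_[scale_ == 0] <- 1
  xs <- sweep(sweep(x, 2, center), 2, scale_, "/")
  n_pcs <- min(n_pcs, ncol(xs), nrow(xs) - 1L)
  pc <- stats::prcomp(xs, center = FALSE, scale. = FALSE, rank. = n_pcs)
  rot <- pc$rotation
  # canonical sign: the largest-magnitude loading of each axis is positive
  flip <- vapply(seq_len(ncol(rot)), function(j) {
    l <- rot[, j]
    sign(l[which.max(abs(l))])
  }, numeric(1))
  flip[flip == 0] <- 1
  rot <- sweep(rot, 2, flip, "*")
  emb <- xs %*% rot
  batch <- rep(c("ref", "query"), c(nrow(ref), nrow(query)))
  if (is.null(n_clusters)) {
    n_clusters <- if (is.null(ref_labels)) 10L else max(10L, length(unique(ref_labels)))
  }
  emb <- .align_batches(emb, batch, n_clusters, n_align_iters, seed)
  structure(list(
    genes = shared, center = center, scale = scale_, rotation = rot,
    n_pcs = n_pcs, n_align_iters = n_align_iters, n_clusters = n_clusters,
    ref_embedding = emb[batch == "ref", , drop = FALSE],
    query_embedding = emb[batch == "query", , drop = FALSE],
    seed = seed
  ), class = "embedding_model")
}

.align_batches <- function(emb, batch, n_clusters, n_iters, seed) {
  if (n_iters < 1) return(emb)
  n_clusters <- min(n_clusters, nrow(emb) - 1L)
  centers <- zm_with_seed(seed,
    stats::kmeans(emb, centers = n_clusters, nstart = 5, iter.max = 50)$centers)
  batches <- unique(batch)
  for (it in seq_len(n_iters)) {
    d2 <- .cross_dist2(emb, centers)
    sigma2 <- mean(apply(d2, 1, min)) + 1e-12
    r <- exp(-d2 / (2 * sigma2))
    r <- r / (rowSums(r) + 1e-300)
    w_tot <- colSums(r)
    mu_global <- crossprod(r, emb) / pmax(w_tot, 1e-12)
    shift <- matrix(0, nrow(emb), ncol(emb))
    for (b in batches) {
      bi <- batch == b
      w_b <- colSums(r[bi, , drop = FALSE])
      mu_b <- crossprod(r[bi, , drop = FALSE], emb[bi, , drop = FALSE]) /
        pmax(w_b, 1e-12)
      # clusters essentially absent from a batch contribute no offset
      offset <- mu_b - mu_global
      offset[w_b < 1e-6, ] <- 0
      shift[bi, ] <- r[bi, , drop = FALSE] %*% offset
    }
    emb <- emb - shift
    centers <- crossprod(r, emb) / pmax(w_tot, 1e-12)
  }
  emb
}

#' Transfer labels by k-NN vote in the aligned embedding
#'
#' Each query cell takes the majority label among its `k` nearest reference
#' cells in the aligned PC space; confidence is the winning vote fraction.
#' Vote ties go to the label with the smaller mean neighbour distance.
#'
#' @param model An `embedding_model` from [fit_joint_embedding()].
#' @param ref_labels Character vector of reference labels (one per
#'   reference cell used in the fit).
#' @param k Number of neighbours (default 15).
#' @return data.frame with `label` and `confidence` per query cell.
#' @export
transfer_labels <- function(model, ref_labels, k = 15) {
  stopifnot(inherits(model, "embedding_model"))
  ref_emb <- model$ref_embedding
  if (length(ref_labels) != nrow(ref_emb)) {
    zm_stop("ref_labels length does not match the reference embedding",
      "zonemap_parameter_error")
  }
  if (k > nrow(ref_emb)) {
    zm_stop("k exceeds the reference size", "zonemap_parameter_error")
  }
  nn <- .knn_cross(model$query_embedding, ref_emb, k)
  n_q <- nrow(model$query_embedding)
  label <- character(n_q)
  confidence <- numeric(n_q)
  for (i in seq_len(n_q)) {
    labs <- ref_labels[nn$index[i, ]]
    tab <- table(labs)
    top <- names(tab)[tab == max(tab)]
    if (length(top) > 1) {
      md <- vapply(top, function(l) mean(nn$distance[i, labs == l]), numeric(1))
      top <- top[which.min(md)]
    }
    label[i] <- top
    confidence[i] <- max(tab) / k
  }
  data.frame(label = label, confidence = confidence, stringsAsFactors = FALSE)
}

#' Concordance and niche enrichment of transferred labels
#'
#' Cross-tabulates transferred (imputed reference) labels against the
#' spatially derived labels, row-normalised so each transferred label's row
#' sums to 1, and computes the fraction of each transferred label's cells
#' falling into each niche.
#'
#' @param spatial_labels Spatially derived labels per cell.
#' @param transferred_labels Transferred labels per cell (same cells, same
#'   order).
#' @param niches Niche labels per cell.
#' @return A list with `concordance` (transferred x spatial, row
#'   stochastic) and `enrichment` (transferred x niche, row stochastic).
#' @export
concordance_and_enrichment <- function(spatial_labels, transferred_labels, niches) {
  if (length(spatial_labels) != length(transferred_labels) ||
      length(spatial_labels) != length(niches)) {
    zm_stop("label vectors are not aligned", "zonemap_alignment_error")
  }
  if (length(spatial_labels) == 0) {
    zm_stop("no cells to summarise", "zonemap_alignment_error")
  }
  conc <- table(transferred = transferred_labels, spatial = spatial_labels)
  conc <- unclass(prop.table(conc, margin = 1))
  enr <- table(transferred = transferred_labels, niche = niches)
  enr <- unclass(prop.table(enr, margin = 1))
  list(concordance = conc, enrichment = enr)
}
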