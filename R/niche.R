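# Niche detection: k-NN neighbourhood matrices (per section, self
# excluded), k-means clustering of neighbourhood rows, manual merging of
# raw clusters into named niches, and composition/proportion summaries.

#' One-hot encoding of cell types
#'
#' @param cells A [cell_table()] with a `cell_type` column.
#' @return Cells x types indicator matrix.
#' @export
one_hot_types <- function(cells) {
  if (!"cell_type" %in% names(cells) || anyNA(cells$cell_type)) {
    zm_stop("cell_type labels are required", "zonemap_schema_error")
  }
  types <- sort(unique(cells$cell_type))
  out <- matrix(0, nrow(cells), length(types), dimnames = list(NULL, types))
  out[cbind(seq_len(nrow(cells)), match(cells$cell_type, types))] <- 1
  out
}

#' Build a weighted k-NN neighbourhood matrix
#'
#' For each cell, finds its `k` nearest neighbours by Euclidean distance on
#' the centroids (self excluded; the search never crosses section
#' boundaries) and replaces the cell's feature row by the weighted mean of
#' its neighbours' rows. Inverse-distance weights are `1 / (d + 1)` (the 1
#' is in the unit of the coordinates, i.e. 1 um for micrometre tables),
#' normalised to sum to 1; `"uniform"` gives each neighbour weight `1/k`.
#' Ties at the k-th distance are broken by `cell_id` order. Sections with
#' `<= k` cells are skipped with a warning and their rows set to `NA`.
#'
#' @param cells A [cell_table()].
#' @param features Row-aligned feature matrix, or `NULL` to use the one-hot
#'   encoding of `cell_type` (composition mode, where every row of the
#'   result sums to 1).
#' @param k Number of neighbours (30 is the protein-imaging default, 50 the
#'   spatial-transcriptomics default).
#' @param weighting `"inverse_distance"` (default) or `"uniform"`.
#' @return Cells x features matrix of weighted neighbour means, aligned to
#'   `cells`.
#' @export
build_neighborhood_matrix <- function(cells, features = NULL, k = 30,
                                      weighting = c("inverse_distance", "uniform")) {
  weighting <- match.arg(weighting)
  stopifnot(inherits(cells, "cell_table"), k >= 1)
  if (is.null(features)) features <- one_hot_types(cells)
  features <- as.matrix(features)
  if (nrow(features) != nrow(cells)) {
    zm_stop("features are not row-aligned to the cell table", "zonemap_integrity_error")
  }
  out <- matrix(NA_real_, nrow(cells), ncol(features),
    dimnames = list(NULL, colnames(features)))
  for (sec in unique(cells$section_id)) {
    idx <- which(cells$section_id == sec)
    if (length(idx) <= k) {
      zm_warn(sprintf("section '%s' has %d cells (<= k = %d); skipped",
        sec, length(idx), k), "zonemap_section_skipped")
      next
    }
    coords <- cbind(cells$x[idx], cells$y[idx])
    tie_rank <- rank(cells$cell_id[idx], ties.method = "first")
    nn <- .knn_brute(coords, k, tie_rank = tie_rank)
    w <- if (weighting == "uniform") {
      matrix(1 / k, length(idx), k)
    } else {
      wi <- 1 / (nn$distance + 1)
      wi / rowSums(wi)
    }
    f <- features[idx, , drop = FALSE]
    for (j in seq_len(ncol(features))) {
      fj <- matrix(f[, j][nn$index], nrow = length(idx))
      out[idx, j] <- rowSums(w * fj)
    }
  }
  out
}

#' Cluster neighbourhood rows into raw niches
#'
#' k-means (10 restarts, fixed seed) on the neighbourhood matrix. Raw
#' labels are renamed by descending cluster size (`"1"` is the largest), so
#' identical partitions get identical names across seeds. Rows that are
#' `NA` (cells of skipped sections) receive `NA` labels.
#'
#' @param nbhd Neighbourhood matrix from [build_neighborhood_matrix()].
#' @param n_clusters Number of clusters.
#' @param seed Integer seed.
#' @return A `niche_clustering` list: `labels` (character, per cell),
#'   `centers`, `sizes`, and `inertia` (total within-cluster sum of
#'   squares).
#' @export
cluster_niches <- function(nbhd, n_clusters, seed = 1L) {
  ok <- stats::complete.cases(nbhd)
  if (n_clusters > sum(ok)) {
    zm_stop("n_clusters exceeds the number of cells", "zonemap_parameter_error")
  }
  km <- zm_with_seed(seed,
    stats::kmeans(nbhd[ok, , drop = FALSE], centers = n_clusters,
      nstart = 10, iter.max = 200))
  sizes <- sort(table(km$cluster), decreasing = TRUE)
  remap <- stats::setNames(as.character(seq_along(sizes)), names(sizes))
  labels <- rep(NA_character_, nrow(nbhd))
  labels[ok] <- remap[as.character(km$cluster)]
  centers <- km$centers[as.integer(names(sizes)), , drop = FALSE]
  rownames(centers) <- as.character(seq_along(sizes))
  structure(list(
    labels = labels,
    centers = centers,
    sizes = as.integer(sizes),
    inertia = km$tot.withinss,
    n_clusters = n_clusters,
    seed = seed
  ), class = "niche_clustering")
}

#' Sweep neighbourhood size and cluster count
#'
#' Reports k-means inertia across a grid of `(k_neighbors, n_clusters)` to
#' support choosing the niche resolution.
#'
#' @param cells A [cell_table()].
#' @param features Feature matrix or `NULL` (one-hot mode).
#' @param k_neighbors,n_clusters Integer vectors defining the grid.
#' @param weighting Passed to [build_neighborhood_matrix()].
#' @param seed Integer seed.
#' @return data.frame of `k_neighbors`, `n_clusters`, `inertia`.
#' @export
niche_sweep <- function(cells, features = NULL, k_neighbors = c(10, 30, 50),
                        n_clusters = 4:8,
                        weighting = "inverse_distance", seed = 1L) {
  grid <- expand.grid(k_neighbors = k_neighbors, n_clusters = n_clusters)
  grid$inertia <- NA_real_
  for (kk in unique(grid$k_neighbors)) {
    nb <- build_neighborhood_matrix(cells, features, k = kk, weighting = weighting)
    for (cc in unique(grid$n_clusters)) {
      cl <- cluster_niches(nb, cc, seed = seed)
      grid$inertia[grid$k_neighbors == kk & grid$n_clusters == cc] <- cl$inertia
    }
  }
  grid
}

#' Merge raw niche clusters into named niches
#'
#' @param labels Raw labels from [cluster_niches()] (`$labels`) .
#' @param merge_map Named character vector or list mapping every raw label
#'   to a final niche name. Must be total over the observed labels.
#' @return Character vector of final niche names (`NA` rows stay `NA`).
#' @export
merge_niches <- function(labels, merge_map) {
  map <- unlist(merge_map)
  seen <- unique(labels[!is.na(labels)])
  unmapped <- setdiff(seen, names(map))
  if (length(unmapped)) {
    zm_stop(paste0("merge map misses raw labels: ", paste(unmapped, collapse = ", ")),
      "zonemap_mapping_error")
  }
  out <- rep(NA_character_, length(labels))
  out[!is.na(labels)] <- unname(map[labels[!is.na(labels)]])
  out
}

#' Cell-type by niche composition table
#'
#' @param cells A [cell_table()] with `cell_type` and `niche` columns.
#' @return A list with `counts` (type x niche integer matrix) and
#'   `log_counts` (`log10(count + 1)`).
#' @export
niche_composition <- function(cells) {
  for (col in c("cell_type", "niche")) {
    if (!col %in% names(cells) || all(is.na(cells[[col]]))) {
      zm_stop(sprintf("column '%s' is required", col), "zonemap_schema_error")
    }
  }
  counts <- table(cell_type = cells$cell_type, niche = cells$niche)
  counts <- unclass(counts)
  list(counts = counts, log_counts = log10(counts + 1))
}

#' Niche proportions per condition
#'
#' @param cells A [cell_table()] with `condition` and `niche` columns.
#' @return Condition x niche matrix of proportions; each row sums to 1.
#' @export
niche_proportions <- function(cells) {
  if (!"niche" %in% names(cells) || all(is.na(cells$niche))) {
    zm_stop("niche labels are required", "zonemap_schema_error")
  }
  tab <- table(condition = cells$condition, niche = cells$niche)
  prop <- prop.table(tab, margin = 1)
  unclass(prop)
}
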