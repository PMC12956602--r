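# Shared internal helpers: classed conditions, seeded evaluation, exact
# nearest-neighbour search. Neighbour search is brute-force but chunked so
# memory stays bounded on sections of tens of thousands of cells.

zm_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "zonemap_error", "error", "condition")))
}

zm_warn <- function(msg, class = "zonemap_warning") {
  warning(warningCondition(msg, class = c(class, "zonemap_warning", "warning", "condition")))
}

#' Evaluate code with a fixed RNG seed
#'
#' Thin wrapper over [withr::with_seed()] used by every stochastic routine in
#' the package so that the caller's RNG stream is never disturbed.
#'
#' @param seed Integer seed.
#' @param code Code to evaluate.
#' @return The value of `code`.
#' @keywords internal
zm_with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# Squared Euclidean cross-distances between two coordinate matrices,
# computed blockwise. Returns the full m x n matrix only when small; callers
# that need row-wise reductions should use .min_cross_dist / .knn_brute.
.cross_dist2 <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  d2 <- outer(rowSums(a^2), rep(1, nrow(b))) +
    outer(rep(1, nrow(a)), rowSums(b^2)) - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  d2
}

# Minimum Euclidean distance from each row of `query` to any row of `ref`.
.min_cross_dist <- function(query, ref, chunk = 2048L) {
  query <- as.matrix(query); ref <- as.matrix(ref)
  n <- nrow(query)
  out <- numeric(n)
  rb2 <- rowSums(ref^2)
  for (lo in seq(1L, n, by = chunk)) {
    hi <- min(lo + chunk - 1L, n)
    q <- query[lo:hi, , drop = FALSE]
    d2 <- outer(rowSums(q^2), rep(1, nrow(ref))) +
      outer(rep(1, nrow(q)), rb2) - 2 * tcrossprod(q, ref)
    out[lo:hi] <- sqrt(pmax(apply(d2, 1L, min), 0))
  }
  out
}

# Exact k nearest neighbours within one coordinate set, self excluded.
# Ties in the k-th distance are broken by `tie_rank` (ascending), so results
# are invariant to the storage order of cells.
.knn_brute <- function(coords, k, tie_rank = NULL, chunk = 1024L) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (k >= n) zm_stop("k must be smaller than the number of points", "zonemap_parameter_error")
  if (is.null(tie_rank)) tie_rank <- seq_len(n)
  idx <- matrix(NA_integer_, n, k)
  dst <- matrix(NA_real_, n, k)
  b2 <- rowSums(coords^2)
  for (lo in seq(1L, n, by = chunk)) {
    hi <- min(lo + chunk - 1L, n)
    q <- coords[lo:hi, , drop = FALSE]
    d2 <- outer(rowSums(q^2), rep(1, n)) +
      outer(rep(1, nrow(q)), b2) - 2 * tcrossprod(q, coords)
    d2[d2 < 0] <- 0
    for (i in seq_len(nrow(q))) {
      gi <- lo + i - 1L
      d <- d2[i, ]
      d[gi] <- Inf
      o <- order(d, tie_rank)[seq_len(k)]
      idx[gi, ] <- o
      dst[gi, ] <- sqrt(d[o])
    }
  }
  list(index = idx, distance = dst)
}

# k nearest rows of `ref` for each row of `query` (cross-set search).
.knn_cross <- function(query, ref, k, chunk = 1024L) {
  query <- as.matrix(query); ref <- as.matrix(ref)
  if (k > nrow(ref)) zm_stop("k exceeds the reference size", "zonemap_parameter_error")
  n <- nrow(query)
  idx <- matrix(NA_integer_, n, k)
  dst <- matrix(NA_real_, n, k)
  rb2 <- rowSums(ref^2)
  for (lo in seq(1L, n, by = chunk)) {
    hi <- min(lo + chunk - 1L, n)
    q <- query[lo:hi, , drop = FALSE]
    d2 <- outer(rowSums(q^2), rep(1, nrow(ref))) +
      outer(rep(1, nrow(q)), rb2) - 2 * tcrossprod(q, ref)
    d2[d2 < 0] <- 0
    for (i in seq_len(nrow(q))) {
      gi <- lo + i - 1L
      o <- order(d2[i, ])[seq_len(k)]
      idx[gi, ] <- o
      dst[gi, ] <- sqrt(d2[i, o])
    }
  }
  list(index = idx, distance = dst)
}
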