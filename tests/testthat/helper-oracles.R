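# Independent oracles and small fixtures used across the suite. The
# oracles deliberately use naive algorithms (full enumeration, O(n^2)
# loops) and never call the implementation paths they check.

# Exact two-sided Mann-Whitney p-value by full enumeration of all
# C(m+n, m) group assignments of the pooled ranks (no ties assumed).
oracle_mw_exact <- function(x, y) {
  m <- length(x); n <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_of <- function(idx) sum(r[idx]) - m * (m + 1) / 2
  u_obs <- u_of(seq_len(m))
  combos <- utils::combn(m + n, m)
  us <- apply(combos, 2, u_of)
  p_le <- mean(us <= u_obs)
  p_ge <- mean(us >= u_obs)
  min(1, 2 * min(p_le, p_ge))
}

# Brute-force Benjamini-Hochberg step-up from the definition:
# q_(i) = min over j >= i of m * p_(j) / j, capped at 1.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    q_sorted[i] <- min(1, min(m * p[o][i:m] / (i:m)))
  }
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# O(n^2) per-cell minimum distance to reference points.
oracle_min_dist <- function(qx, qy, rx, ry) {
  vapply(seq_along(qx), function(i) {
    min(sqrt((qx[i] - rx)^2 + (qy[i] - ry)^2))
  }, numeric(1))
}

# O(n^2) weighted k-NN neighbourhood rows (self excluded, inverse-distance
# weights 1/(d+1), ties at the k-th distance broken by cell id order).
oracle_neighborhood <- function(x, y, ids, feats, k, weighting = "inverse_distance") {
  n <- length(x)
  out <- matrix(NA_real_, n, ncol(feats))
  tie <- rank(ids, ties.method = "first")
  for (i in seq_len(n)) {
    d <- sqrt((x[i] - x)^2 + (y[i] - y)^2)
    d[i] <- Inf
    o <- order(d, tie)[seq_len(k)]
    w <- if (weighting == "uniform") rep(1 / k, k) else {
      wi <- 1 / (d[o] + 1)
      wi / sum(wi)
    }
    out[i, ] <- colSums(w * feats[o, , drop = FALSE])
  }
  out
}

# Grid search for the equal-weighted-density point of a planted
# two-component normal mixture between its means.
oracle_mixture_gate <- function(w1, m1, s1, w2, m2, s2, n_grid = 40001) {
  xs <- seq(m1, m2, length.out = n_grid)
  d <- w1 * stats::dnorm(xs, m1, s1) - w2 * stats::dnorm(xs, m2, s2)
  xs[which.min(abs(d))]
}

# Minimal cell table fixture: n cells uniform in a box, one section.
make_cells <- function(n, width = 100, height = 100, section = "s1",
                       condition = "H", seed = 1, types = NULL) {
  withr::with_seed(seed, {
    df <- data.frame(
      cell_id = sprintf("c%04d", seq_len(n)),
      section_id = section,
      condition = condition,
      x = stats::runif(n, 0, width),
      y = stats::runif(n, 0, height)
    )
    if (!is.null(types)) df$cell_type <- sample(types, n, replace = TRUE)
    cell_table(df)
  })
}
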