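# Shared statistical kernels: the Mann-Whitney rank-sum test, rank-sum
# differential expression with fold changes, Benjamini-Hochberg adjustment,
# normalised-scaled dot-plot means, and gene-signature scoring.

#' Two-sided Mann-Whitney U test
#'
#' The shared rank-sum kernel of the package. Uses the exact null
#' distribution when the combined sample size is at most 20 (via the
#' standard distribution without ties, and full enumeration of group
#' assignments when ties are present), and the normal approximation with
#' tie correction and continuity correction for larger samples.
#'
#' @param x,y Numeric samples.
#' @return A list with `U` (the smaller of the two U statistics), `U_x`
#'   (the U statistic of `x` versus `y`), and `p` (two-sided).
#' @export
mann_whitney_u <- function(x, y) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  m <- length(x); n <- length(y)
  if (m < 1 || n < 1) {
    zm_stop("both groups must be non-empty", "zonemap_parameter_error")
  }
  mn <- m * n
  if (length(unique(c(x, y))) == 1) {
    # fully tied data carry no rank information
    return(list(U = mn / 2, U_x = mn / 2, p = 1))
  }
  ties <- anyDuplicated(c(x, y)) > 0
  small <- (m + n) <= 20
  if (small && ties) {
    # exact permutation null over all group assignments of the tied ranks
    r <- rank(c(x, y))
    u_x <- sum(r[seq_len(m)]) - m * (m + 1) / 2
    us <- utils::combn(m + n, m, FUN = function(idx) sum(r[idx])) -
      m * (m + 1) / 2
    p <- min(1, 2 * min(mean(us <= u_x), mean(us >= u_x)))
    return(list(U = min(u_x, mn - u_x), U_x = u_x, p = p))
  }
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = small, correct = TRUE))
  u_x <- unname(wt$statistic)
  p <- wt$p.value
  if (!is.finite(p)) p <- 1
  list(U = min(u_x, mn - u_x), U_x = u_x, p = min(1, p))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param pvals Numeric vector of p-values in `[0, 1]`.
#' @return q-values of the same length (monotone step-up, capped at 1).
#' @export
bh_adjust <- function(pvals) {
  if (any(!is.na(pvals) & (pvals < 0 | pvals > 1))) {
    zm_stop("p-values must lie in [0, 1]", "zonemap_value_error")
  }
  stats::p.adjust(pvals, method = "BH")
}

#' Library-size normalised log1p expression
#'
#' Transcript counts are scaled per cell to `target` total counts and
#' log1p-transformed; protein intensities are log1p-transformed without
#' library-size scaling. Cells with zero total counts stay all-zero.
#'
#' @param features A [feature_matrix()].
#' @param target Library-size target (default 10,000 counts per cell).
#' @return A list with `lognorm` (log1p of normalised values) and `norm`
#'   (normalised values on the linear scale).
#' @export
normalize_features <- function(features, target = 1e4) {
  vals <- unclass(features)
  if (modality(features) == "transcript_count") {
    libsize <- rowSums(vals)
    scale <- ifelse(libsize > 0, target / libsize, 0)
    norm <- vals * scale
  } else {
    norm <- vals
  }
  list(lognorm = log1p(norm), norm = norm)
}

#' Rank-sum differential expression between two conditions
#'
#' Cell-level two-sided rank-sum test per gene on library-size-normalised
#' log1p values, comparing condition P against H. The log2 fold change is
#' computed from the group means of the normalised (linear-scale) values
#' with a 1e-9 pseudocount; p-values are Benjamini-Hochberg corrected over
#' the tested genes. Genes with zero counts in every cell are excluded with
#' a message.
#'
#' @param features A [feature_matrix()].
#' @param condition Character vector per cell, values `"H"` or `"P"`.
#' @param pseudobulk If `TRUE`, test subject-level mean normalised values
#'   instead of cells; requires `subject`.
#' @param subject Subject id per cell (only used for pseudobulk).
#' @return A `de_result` data.frame ordered by `q`: `gene`, `lfc` (log2
#'   P/H), `p`, `q`, `mean_H`, `mean_P`.
#' @export
wilcoxon_de <- function(features, condition, pseudobulk = FALSE, subject = NULL) {
  stopifnot(length(condition) == nrow(features))
  if (!all(condition %in% c("H", "P"))) {
    zm_stop("condition must be 'H' or 'P' for every cell", "zonemap_schema_error")
  }
  if (sum(condition == "H") < 2 || sum(condition == "P") < 2) {
    zm_stop("at least 2 cells per condition are required", "zonemap_parameter_error")
  }
  nz <- colSums(unclass(features)) > 0
  if (any(!nz)) {
    message(sprintf("excluded %d gene(s) with zero counts everywhere", sum(!nz)))
  }
  genes <- colnames(features)[nz]
  nf <- normalize_features(features)
  lognorm <- nf$lognorm[, genes, drop = FALSE]
  norm <- nf$norm[, genes, drop = FALSE]
  if (pseudobulk) {
    if (is.null(subject)) zm_stop("pseudobulk requires subject ids", "zonemap_parameter_error")
    agg_l <- rowsum(lognorm, subject) / as.vector(table(subject)[sort(unique(subject))])
    agg_l <- agg_l[sort(unique(subject)), , drop = FALSE]
    agg_n <- rowsum(norm, subject) / as.vector(table(subject)[sort(unique(subject))])
    agg_n <- agg_n[sort(unique(subject)), , drop = FALSE]
    cond <- condition[match(rownames(agg_l), subject)]
    lognorm <- agg_l; norm <- agg_n; condition <- cond
  }
  is_p <- condition == "P"
  res <- lapply(genes, function(g) {
    mw <- mann_whitney_u(lognorm[is_p, g], lognorm[!is_p, g])
    m_h <- mean(norm[!is_p, g]); m_p <- mean(norm[is_p, g])
    data.frame(
      gene = g,
      lfc = log2((m_p + 1e-9) / (m_h + 1e-9)),
      p = mw$p,
      mean_H = m_h, mean_P = m_p,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, res)
  out$q <- bh_adjust(out$p)
  out <- out[order(out$q, out$p, out$gene), c("gene", "lfc", "p", "q", "mean_H", "mean_P")]
  rownames(out) <- NULL
  class(out) <- c("de_result", class(out))
  out
}

#' Normalised and scaled group means for dot plots
#'
#' Library-size normalises and log1p-transforms expression, takes the mean
#' per (group, gene), and z-scores each gene's means across groups using
#' the population standard deviation. Genes with zero variance across
#' groups get scaled mean 0. The fraction of cells expressing (count > 0,
#' or gated > 0.5 for protein) is reported alongside.
#'
#' @param features A [feature_matrix()].
#' @param groups Character vector of group labels per cell.
#' @return A `dotplot_stat` data.frame: `group`, `gene`, `mean_lognorm`,
#'   `scaled_mean`, `frac_expressing`.
#' @export
dotplot_stats <- function(features, groups) {
  stopifnot(length(groups) == nrow(features))
  groups <- as.character(groups)
  keep <- !is.na(groups)
  lognorm <- normalize_features(features)$lognorm[keep, , drop = FALSE]
  vals <- unclass(features)[keep, , drop = FALSE]
  groups <- groups[keep]
  glev <- sort(unique(groups))
  expr_cut <- if (modality(features) == "transcript_count") 0 else 0.5
  gmeans <- rowsum(lognorm, groups)[glev, , drop = FALSE] /
    as.vector(table(groups)[glev])
  gfrac <- rowsum((vals > expr_cut) * 1, groups)[glev, , drop = FALSE] /
    as.vector(table(groups)[glev])
  center <- colMeans(gmeans)
  pop_sd <- sqrt(colMeans(sweep(gmeans, 2, center)^2))
  scaled <- sweep(gmeans, 2, center)
  scaled <- sweep(scaled, 2, ifelse(pop_sd > 0, pop_sd, 1), "/")
  scaled[, pop_sd == 0] <- 0
  out <- data.frame(
    group = rep(glev, times = ncol(gmeans)),
    gene = rep(colnames(gmeans), each = length(glev)),
    mean_lognorm = as.vector(gmeans),
    scaled_mean = as.vector(scaled),
    frac_expressing = as.vector(gfrac),
    stringsAsFactors = FALSE
  )
  class(out) <- c("dotplot_stat", class(out))
  out
}

#' Per-cell gene-signature score
#'
#' The mean over the signature genes of per-gene z-scored normalised log1p
#' expression (z-scored across cells). Signature genes missing from the
#' matrix are dropped with a warning; an empty intersection is an error.
#' Used, for instance, to call high-endothelial-venule-like cells from an
#' HEV-associated gene set.
#'
#' @param features A [feature_matrix()].
#' @param gene_set Character vector of signature genes.
#' @return Numeric vector of per-cell scores.
#' @export
signature_score <- function(features, gene_set) {
  present <- intersect(gene_set, colnames(features))
  if (!length(present)) {
    zm_stop("no signature genes present in the feature matrix", "zonemap_signature_error")
  }
  dropped <- setdiff(gene_set, present)
  if (length(dropped)) {
    zm_warn(paste0("signature genes missing and dropped: ", paste(dropped, collapse = ", ")),
      "zonemap_signature_warning")
  }
  lognorm <- normalize_features(features)$lognorm[, present, drop = FALSE]
  mu <- colMeans(lognorm)
  sd_ <- apply(lognorm, 2, stats::sd)
  sd_[sd_ == 0] <- 1
  z <- sweep(sweep(lognorm, 2, mu), 2, sd_, "/")
  rowMeans(z)
}
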