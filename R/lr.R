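# Ligand-receptor coexpression within niches: load an OmniPath-style pair
# table, score fraction-based coexpression per niche, attribute each gene's
# predominant expressing cell type, and emit a tidy heatmap table.

#' Load a ligand-receptor pair table
#'
#' Expects a TSV with a header and at least two columns (ligand, receptor);
#' extra columns are kept as annotation. Duplicate pairs are deduplicated
#' with a warning. Genes absent from the feature panel are flagged at
#' scoring time, not here.
#'
#' @param path TSV file path.
#' @return An `lr_pair_table` data.frame with columns `ligand`, `receptor`.
#' @export
load_pairs <- function(path) {
  if (!file.exists(path)) zm_stop(sprintf("file not found: %s", path), "zonemap_io_error")
  raw <- tryCatch(
    utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE),
    error = function(e) zm_stop("empty or unreadable pair file", "zonemap_format_error")
  )
  if (ncol(raw) < 2) zm_stop("pair table needs at least 2 columns", "zonemap_format_error")
  if (nrow(raw) == 0) {
    zm_warn("pair table has a header but no rows", "zonemap_format_warning")
  }
  names(raw)[1:2] <- c("ligand", "receptor")
  if (any(!nzchar(raw$ligand)) || any(!nzchar(raw$receptor))) {
    zm_stop("gene names must be non-empty", "zonemap_format_error")
  }
  key <- paste(raw$ligand, raw$receptor, sep = "\r")
  if (anyDuplicated(key)) {
    zm_warn(sprintf("%d duplicated pair(s) removed", sum(duplicated(key))),
      "zonemap_format_warning")
    raw <- raw[!duplicated(key), , drop = FALSE]
  }
  rownames(raw) <- NULL
  class(raw) <- c("lr_pair_table", class(raw))
  raw
}

#' Score ligand-receptor coexpression within niches
#'
#' For each niche, the fraction of cells expressing each pair gene
#' (count > 0) is computed; a pair is coexpressed in a niche when both
#' fractions reach `fraction_cutoff`, and its score is the smaller of the
#' two fractions. Scaled means across niches follow [dotplot_stats()]. The
#' predominant cell type per (gene, niche) is the type with the highest
#' mean normalised expression among types with at least `min_type_cells`
#' cells in the niche. Pairs with a gene absent from the panel are skipped
#' and listed in the `skipped` attribute.
#'
#' @param cells A [cell_table()] with `niche` and `cell_type` columns.
#' @param features Row-aligned [feature_matrix()].
#' @param pairs An `lr_pair_table` from [load_pairs()].
#' @param fraction_cutoff Minimum expressing fraction for both genes
#'   (default 0.1).
#' @param min_type_cells Minimum cells of a type in a niche for
#'   predominant-type attribution (default 10).
#' @return An `lr_pair_score` list: `pair_scores` (niche x pair rows with
#'   fractions, score, coexpressed flag, scaled means),
#'   `predominant_types` (niche x gene rows), and attributes.
#' @export
niche_lr_scores <- function(cells, features, pairs, fraction_cutoff = 0.1,
                            min_type_cells = 10) {
  for (col in c("niche", "cell_type")) {
    if (!col %in% names(cells) || all(is.na(cells[[col]]))) {
      zm_stop(sprintf("column '%s' is required", col), "zonemap_schema_error")
    }
  }
  present <- colnames(features)
  usable <- pairs$ligand %in% present & pairs$receptor %in% present
  skipped <- pairs[!usable, c("ligand", "receptor")]
  pairs <- pairs[usable, , drop = FALSE]
  genes <- unique(c(pairs$ligand, pairs$receptor))
  niches <- sort(unique(cells$niche[!is.na(cells$niche)]))

  expr_cut <- if (modality(features) == "transcript_count") 0 else 0.5
  expressing <- unclass(features)[, genes, drop = FALSE] > expr_cut
  lognorm <- normalize_features(features)$lognorm[, genes, drop = FALSE]

  # fraction expressing and scaled means per niche
  dp <- dotplot_stats(
    structure(unclass(features)[, genes, drop = FALSE],
      modality = modality(features), class = class(features)),
    ifelse(is.na(cells$niche), NA, cells$niche)
  )
  frac <- matrix(NA_real_, length(niches), length(genes),
    dimnames = list(niches, genes))
  scl <- frac
  for (i in seq_len(nrow(dp))) {
    frac[dp$group[i], dp$gene[i]] <- dp$frac_expressing[i]
    scl[dp$group[i], dp$gene[i]] <- dp$scaled_mean[i]
  }

  pair_rows <- list()
  for (nh in niches) {
    for (i in seq_len(nrow(pairs))) {
      lg <- pairs$ligand[i]; rc <- pairs$receptor[i]
      fl <- frac[nh, lg]; fr <- frac[nh, rc]
      pair_rows[[length(pair_rows) + 1L]] <- data.frame(
        niche = nh, ligand = lg, receptor = rc,
        ligand_fraction = fl, receptor_fraction = fr,
        ligand_scaled_mean = scl[nh, lg], receptor_scaled_mean = scl[nh, rc],
        score = min(fl, fr),
        coexpressed = fl >= fraction_cutoff & fr >= fraction_cutoff,
        stringsAsFactors = FALSE
      )
    }
  }
  pair_scores <- do.call(rbind, pair_rows)

  # predominant expressing cell type per (niche, gene)
  type_rows <- list()
  for (nh in niches) {
    in_niche <- which(!is.na(cells$niche) & cells$niche == nh)
    tt <- table(cells$cell_type[in_niche])
    ok_types <- names(tt)[tt >= min_type_cells]
    for (g in genes) {
      ptype <- NA_character_
      if (length(ok_types)) {
        m <- vapply(ok_types, function(ty) {
          mean(lognorm[in_niche[cells$cell_type[in_niche] == ty], g])
        }, numeric(1))
        ptype <- ok_types[which.max(m)]
      }
      type_rows[[length(type_rows) + 1L]] <- data.frame(
        niche = nh, gene = g, predominant_type = ptype,
        stringsAsFactors = FALSE
      )
    }
  }
  structure(list(
    pair_scores = pair_scores,
    predominant_types = do.call(rbind, type_rows),
    fraction_cutoff = fraction_cutoff,
    skipped = skipped
  ), class = "lr_pair_score")
}

#' Tidy table of coexpressed ligand-receptor pairs for plotting
#'
#' Retains only coexpressed pairs and expands each into one row per role
#' (ligand, receptor) with its scaled mean and predominant cell type, rows
#' ordered by niche then descending score (deterministic sort keys).
#'
#' @param scores An `lr_pair_score` from [niche_lr_scores()].
#' @return A data.frame with columns `niche`, `pair`, `role`, `gene`,
#'   `scaled_mean`, `score`, `predominant_type`. Empty (zero-row) when no
#'   pair is coexpressed.
#' @export
lr_heatmap_table <- function(scores) {
  stopifnot(inherits(scores, "lr_pair_score"))
  ps <- scores$pair_scores[scores$pair_scores$coexpressed, , drop = FALSE]
  ps <- ps[order(ps$niche, -ps$score, ps$ligand, ps$receptor), , drop = FALSE]
  if (nrow(ps) == 0) {
    return(data.frame(
      niche = character(), pair = character(), role = character(),
      gene = character(), scaled_mean = numeric(), score = numeric(),
      predominant_type = character(), stringsAsFactors = FALSE
    ))
  }
  pt <- scores$predominant_types
  ptype <- function(nh, g) {
    v <- pt$predominant_type[pt$niche == nh & pt$gene == g]
    if (length(v)) v[1] else NA_character_
  }
  rows <- lapply(seq_len(nrow(ps)), function(i) {
    r <- ps[i, ]
    pair <- paste(r$ligand, r$receptor, sep = "-")
    data.frame(
      niche = r$niche, pair = pair,
      role = c("ligand", "receptor"),
      gene = c(r$ligand, r$receptor),
      scaled_mean = c(r$ligand_scaled_mean, r$receptor_scaled_mean),
      score = r$score,
      predominant_type = c(ptype(r$niche, r$ligand), ptype(r$niche, r$receptor)),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
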