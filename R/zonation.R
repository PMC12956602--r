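# Barrier-proximity zonation: section filtering by reference-niche cell
# count, exact nearest-reference distances, per-niche proximity summaries
# under a maximum-distance threshold, and the distance-binned stromal
# expression comparison between conditions.

#' Filter sections by reference-niche cell count
#'
#' Keeps the sections with at least `min_cells` cells of the reference
#' niche (default 200, the robustness threshold for proximity summaries).
#' Excluded sections are reported with their counts via a message.
#'
#' @param cells A [cell_table()] with a `niche` column.
#' @param ref_niche Name of the reference niche (e.g. `"TAE"`).
#' @param min_cells Minimum reference-cell count per section.
#' @return Character vector of eligible section ids.
#' @export
filter_sections <- function(cells, ref_niche, min_cells = 200) {
  if (!"niche" %in% names(cells)) {
    zm_stop("niche labels are required", "zonemap_schema_error")
  }
  if (nrow(cells) == 0) return(character())
  if (!ref_niche %in% cells$niche) {
    zm_stop(sprintf("reference niche '%s' absent from the label set", ref_niche),
      "zonemap_parameter_error")
  }
  sections <- unique(cells$section_id)
  counts <- vapply(sections, function(s) {
    sum(cells$section_id == s & cells$niche == ref_niche, na.rm = TRUE)
  }, numeric(1))
  excluded <- sections[counts < min_cells]
  if (length(excluded)) {
    message(sprintf("excluded %d section(s) with < %d '%s' cells: %s",
      length(excluded), min_cells, ref_niche,
      paste(sprintf("%s (%d)", excluded, counts[counts < min_cells]), collapse = ", ")))
  }
  sections[counts >= min_cells]
}

#' Per-cell minimum distance to a reference niche
#'
#' Exact (non-approximate) Euclidean distance from each cell's centroid to
#' the nearest cell of the reference niche, computed within each section.
#' Reference cells get distance 0; cells of sections without reference
#' cells get `NA` with a warning.
#'
#' @param cells A [cell_table()] with a `niche` column.
#' @param ref_niche Reference niche name.
#' @return Numeric vector of distances, aligned to `cells`, in the unit of
#'   the coordinates.
#' @export
distance_to_reference <- function(cells, ref_niche) {
  if (!"niche" %in% names(cells)) {
    zm_stop("niche labels are required", "zonemap_schema_error")
  }
  out <- rep(NA_real_, nrow(cells))
  for (sec in unique(cells$section_id)) {
    idx <- which(cells$section_id == sec)
    is_ref <- cells$niche[idx] == ref_niche & !is.na(cells$niche[idx])
    if (!any(is_ref)) {
      zm_warn(sprintf("section '%s' has no '%s' cells; skipped", sec, ref_niche),
        "zonemap_section_skipped")
      next
    }
    ref_xy <- cbind(cells$x[idx][is_ref], cells$y[idx][is_ref])
    qry <- which(!is_ref)
    out[idx[is_ref]] <- 0
    if (length(qry)) {
      qry_xy <- cbind(cells$x[idx][qry], cells$y[idx][qry])
      out[idx[qry]] <- .min_cross_dist(qry_xy, ref_xy)
    }
  }
  out
}

#' Proximity summary of immune niches to a reference niche
#'
#' For every (section, immune niche) pair, counts the niche cells whose
#' minimum distance to the reference niche is within `max_distance`
#' (inclusive) and reports the mean of those distances. The default
#' `method = "min"` averages per-cell minimum distances (zonal depth); the
#' `"allpairs"` alternative averages all reference-to-niche pairwise
#' distances within the threshold.
#'
#' @param cells A [cell_table()] with `niche` labels, pre-filtered with
#'   [filter_sections()].
#' @param ref_niche Reference niche name.
#' @param immune_niches Character vector of niches to summarise.
#' @param max_distance Distance threshold in the unit of the table
#'   (default 3000, matched to pixel-unit imaging tables; convert with
#'   [to_um()] for micrometre analyses).
#' @param method `"min"` (default) or `"allpairs"`.
#' @return A `zonation_summary` data.frame: `section_id`, `niche`,
#'   `n_within`, `mean_distance` (NA when `n_within` is 0), plus the
#'   threshold used.
#' @export
niche_distance_summary <- function(cells, ref_niche, immune_niches,
                                   max_distance = 3000,
                                   method = c("min", "allpairs")) {
  method <- match.arg(method)
  dmin <- distance_to_reference(cells, ref_niche)
  rows <- list()
  for (sec in unique(cells$section_id)) {
    sec_idx <- cells$section_id == sec
    for (nh in immune_niches) {
      idx <- which(sec_idx & !is.na(cells$niche) & cells$niche == nh)
      if (method == "min" || length(idx) == 0) {
        d <- dmin[idx]
        d <- d[!is.na(d) & d <= max_distance]
      } else {
        ref_idx <- which(sec_idx & cells$niche == ref_niche)
        d2 <- .cross_dist2(
          cbind(cells$x[idx], cells$y[idx]),
          cbind(cells$x[ref_idx], cells$y[ref_idx])
        )
        d <- sqrt(d2[d2 <= max_distance^2])
      }
      n_within <- if (method == "min") length(d) else {
        sum(!is.na(dmin[idx]) & dmin[idx] <= max_distance)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        section_id = sec, niche = nh,
        n_within = n_within,
        mean_distance = if (length(d)) mean(d) else NA_real_,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "max_distance") <- max_distance
  attr(out, "ref_niche") <- ref_niche
  attr(out, "method") <- method
  class(out) <- c("zonation_summary", class(out))
  out
}

#' Proportion of stromal cells expressing genes, by distance bin
#'
#' Computes per-cell minimum distances to the reference niche (in the unit
#' of the table, expected micrometres), assigns stromal cells to half-open
#' distance bins (`[0,100)`, `[100,500)`, `[500,1500)` um by default; cells
#' at or beyond the last edge are excluded), pools sections within subject,
#' and reports the per-subject proportion of stromal cells expressing each
#' gene. "Expressing" means count > 0 for transcript matrices and gated
#' value > 0.5 for protein matrices.
#'
#' @param cells A [cell_table()] with `niche` and `cell_type` columns.
#' @param features Row-aligned [feature_matrix()].
#' @param stromal_types Cell types forming the stromal compartment.
#' @param genes Genes to profile (default: all).
#' @param ref_niche Reference niche for distances (default `"TAE"`).
#' @param bins Numeric vector of bin edges in micrometres.
#' @param distances Optional precomputed per-cell distances (skips the
#'   internal [distance_to_reference()] call).
#' @return A `distance_bin_profile` data.frame: `subject_id`, `condition`,
#'   `bin`, `gene`, `n_stromal`, `proportion` (NA when a subject has no
#'   stromal cells in a bin, which is also messaged).
#' @export
bin_stromal_expression <- function(cells, features, stromal_types,
                                   genes = colnames(features),
                                   ref_niche = "TAE",
                                   bins = c(0, 100, 500, 1500),
                                   distances = NULL) {
  stopifnot(length(bins) >= 2)
  missing <- setdiff(genes, colnames(features))
  if (length(missing)) {
    zm_stop(paste0("genes absent from the feature matrix: ", paste(missing, collapse = ", ")),
      "zonemap_schema_error")
  }
  if (is.null(distances)) distances <- distance_to_reference(cells, ref_niche)
  expressing <- if (modality(features) == "transcript_count") {
    unclass(features[, genes, drop = FALSE]) > 0
  } else {
    unclass(features[, genes, drop = FALSE]) > 0.5
  }
  bin_labels <- sprintf("[%g,%g)", bins[-length(bins)], bins[-1])
  bin_of <- cut(distances, breaks = bins, right = FALSE, labels = bin_labels)
  stromal <- cells$cell_type %in% stromal_types
  rows <- list()
  subjects <- unique(cells$subject_id)
  for (sb in subjects) {
    cond <- cells$condition[match(sb, cells$subject_id)]
    for (bi in seq_along(bin_labels)) {
      sel <- which(stromal & cells$subject_id == sb & !is.na(bin_of) &
        bin_of == bin_labels[bi])
      if (!length(sel)) {
        message(sprintf("subject '%s' has no stromal cells in bin %s", sb, bin_labels[bi]))
      }
      for (g in genes) {
        rows[[length(rows) + 1L]] <- data.frame(
          subject_id = sb, condition = cond,
          bin = bin_labels[bi], gene = g,
          n_stromal = length(sel),
          proportion = if (length(sel)) mean(expressing[sel, g]) else NA_real_,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "bins") <- bins
  attr(out, "ref_niche") <- ref_niche
  class(out) <- c("distance_bin_profile", class(out))
  out
}

.classify_p <- function(p) {
  ifelse(is.na(p), "untestable",
    ifelse(p <= 0.05, "significant",
      ifelse(p <= 0.1, "trend", "ns")))
}

#' Compare per-subject expressing proportions between conditions
#'
#' For every (bin, gene), runs a two-sided Mann-Whitney U test on the
#' subject-level proportions of condition H versus P (exact null for
#' combined n at most 20 without ties, normal approximation with tie and
#' continuity correction otherwise) and classifies the result:
#' `significant` (p <= 0.05), `trend` (0.05 < p <= 0.1), `ns` otherwise.
#' Bin/gene combinations without at least 2 defined proportions per group
#' are marked `untestable`.
#'
#' @param profile A `distance_bin_profile` from [bin_stromal_expression()].
#' @return data.frame of `bin`, `gene`, `n_H`, `n_P`, `U` (the smaller of
#'   the two U statistics), `p`, `class`.
#' @export
compare_groups <- function(profile) {
  stopifnot(inherits(profile, "distance_bin_profile"))
  combos <- unique(profile[c("bin", "gene")])
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    sub <- profile[profile$bin == combos$bin[i] & profile$gene == combos$gene[i], ]
    xh <- sub$proportion[sub$condition == "H"]
    xp <- sub$proportion[sub$condition == "P"]
    xh <- xh[!is.na(xh)]; xp <- xp[!is.na(xp)]
    if (length(xh) < 2 || length(xp) < 2) {
      return(data.frame(
        bin = combos$bin[i], gene = combos$gene[i],
        n_H = length(xh), n_P = length(xp),
        U = NA_real_, p = NA_real_, class = "untestable",
        stringsAsFactors = FALSE
      ))
    }
    mw <- mann_whitney_u(xh, xp)
    data.frame(
      bin = combos$bin[i], gene = combos$gene[i],
      n_H = length(xh), n_P = length(xp),
      U = mw$U, p = mw$p, class = .classify_p(mw$p),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
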