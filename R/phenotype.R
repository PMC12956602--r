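# Hierarchical rule-based phenotype assignment on gated marker values,
# k-means subclustering within a phenotype, and region annotation from
# pathologist-drawn ROIs.

#' Construct a phenotype rule set
#'
#' An ordered hierarchy of rules. Each rule names a phenotype, its parent
#' (`NA` or `"root"` for top-level rules), and marker requirements grouped
#' by modifier: `pos`/`allpos` markers must all exceed 0.5 on the gated
#' scale, at least one `anypos` marker must exceed 0.5, and all `neg`
#' markers must be at or below 0.5.
#'
#' @param rules A list; each element a list with `phenotype`, `parent`
#'   (optional), and any of `pos`, `allpos`, `anypos`, `neg` (character
#'   vectors of marker names).
#' @return A `phenotype_rules` object.
#' @export
phenotype_rules <- function(rules) {
  parsed <- lapply(rules, function(r) {
    stopifnot(!is.null(r$phenotype))
    parent <- r$parent
    if (is.null(parent) || is.na(parent) || identical(parent, "")) parent <- "root"
    list(
      phenotype = as.character(r$phenotype),
      parent = as.character(parent),
      pos = as.character(c(r$pos, r$allpos)),
      anypos = as.character(r$anypos %||% character()),
      neg = as.character(r$neg %||% character())
    )
  })
  names(parsed) <- vapply(parsed, `[[`, character(1), "phenotype")
  if (anyDuplicated(names(parsed))) {
    zm_stop("duplicate phenotype names in rule set", "zonemap_schema_error")
  }
  declared <- character()
  for (r in parsed) {
    if (r$parent != "root" && !r$parent %in% declared) {
      zm_stop(sprintf("rule '%s' references parent '%s' before it is declared",
        r$phenotype, r$parent), "zonemap_schema_error")
    }
    declared <- c(declared, r$phenotype)
  }
  structure(parsed, class = "phenotype_rules")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a phenotype rule set from YAML
#'
#' The YAML is a sequence of mappings, each with `phenotype`, optional
#' `parent`, and marker lists under `pos`, `allpos`, `anypos`, `neg`.
#'
#' @param path YAML file path.
#' @return A [phenotype_rules()] object.
#' @export
read_phenotype_rules <- function(path) {
  if (!file.exists(path)) zm_stop(sprintf("file not found: %s", path), "zonemap_io_error")
  phenotype_rules(yaml::read_yaml(path))
}

.rule_matches <- function(rule, gated) {
  n <- nrow(gated)
  ok <- rep(TRUE, n)
  for (mk in rule$pos) ok <- ok & gated[, mk] > 0.5
  if (length(rule$anypos)) {
    any_ok <- rep(FALSE, n)
    for (mk in rule$anypos) any_ok <- any_ok | gated[, mk] > 0.5
    ok <- ok & any_ok
  }
  for (mk in rule$neg) ok <- ok & gated[, mk] <= 0.5
  ok
}

.rule_score <- function(rule, gated) {
  mks <- if (length(rule$pos)) rule$pos else rule$anypos
  if (!length(mks)) return(rep(0, nrow(gated)))
  rowMeans(gated[, mks, drop = FALSE])
}

#' Assign phenotypes by walking a rule hierarchy
#'
#' Each cell starts at the root and repeatedly descends to the deepest
#' matching rule. Among matching sibling rules the one with the larger mean
#' of its positive-marker gated values wins (declaration order breaks exact
#' ties). Cells matching no top-level rule are labelled `"unknown"`.
#'
#' @param gated Matrix of gated values in `[0, 1]` (from [rescale_gated()]).
#' @param rules A [phenotype_rules()] object.
#' @return Character vector of phenotype labels, one per cell.
#' @export
assign_phenotypes <- function(gated, rules) {
  stopifnot(inherits(rules, "phenotype_rules"))
  used <- unique(unlist(lapply(rules, function(r) c(r$pos, r$anypos, r$neg))))
  missing <- setdiff(used, colnames(gated))
  if (length(missing)) {
    zm_stop(paste0("rules reference unknown markers: ", paste(missing, collapse = ", ")),
      "zonemap_schema_error")
  }
  if (any(gated < 0 | gated > 1, na.rm = TRUE)) {
    zm_stop("gated values must lie in [0, 1]", "zonemap_schema_error")
  }
  n <- nrow(gated)
  label <- rep("root", n)
  active <- rep(TRUE, n)
  parents <- vapply(rules, `[[`, character(1), "parent")
  while (any(active)) {
    progressed <- rep(FALSE, n)
    for (lab in unique(label[active])) {
      at <- which(active & label == lab)
      kids <- which(parents == lab)
      if (!length(kids)) next
      best_score <- rep(-Inf, length(at))
      best_lab <- rep(NA_character_, length(at))
      for (ki in kids) {
        r <- rules[[ki]]
        m <- .rule_matches(r, gated[at, , drop = FALSE])
        s <- .rule_score(r, gated[at, , drop = FALSE])
        # strict > keeps declaration order as the tie-break
        take <- m & s > best_score
        best_score[take] <- s[take]
        best_lab[take] <- r$phenotype
      }
      hit <- !is.na(best_lab)
      label[at[hit]] <- best_lab[hit]
      progressed[at[hit]] <- TRUE
      active[at[!hit]] <- FALSE
    }
    active <- active & progressed
  }
  label[label == "root"] <- "unknown"
  label
}

#' Subcluster one phenotype with k-means
#'
#' Splits only the cells carrying `target` into `k` clusters by k-means
#' (Euclidean, 10 restarts, fixed seed) on the gated values of `markers`
#' (default: all columns). New labels are `"<target>.<i>"` with clusters
#' numbered by descending size; all other cells keep their labels.
#'
#' @param gated Matrix of gated (rescaled) marker values.
#' @param labels Current phenotype labels (one per row of `gated`).
#' @param target Phenotype to split.
#' @param k Number of subclusters.
#' @param markers Optional marker subset used for clustering.
#' @param seed Integer seed.
#' @return The refined label vector.
#' @export
subcluster <- function(gated, labels, target, k, markers = colnames(gated), seed = 1L) {
  idx <- which(labels == target)
  if (length(idx) < k) {
    zm_stop(sprintf("phenotype '%s' has %d cells, fewer than k = %d",
      target, length(idx), k), "zonemap_clustering_error")
  }
  missing <- setdiff(markers, colnames(gated))
  if (length(missing)) {
    zm_stop(paste0("unknown markers: ", paste(missing, collapse = ", ")),
      "zonemap_schema_error")
  }
  x <- gated[idx, markers, drop = FALSE]
  cl <- if (k == 1) rep(1L, length(idx)) else {
    zm_with_seed(seed, stats::kmeans(x, centers = k, nstart = 10, iter.max = 100)$cluster)
  }
  sizes <- sort(table(cl), decreasing = TRUE)
  remap <- stats::setNames(seq_along(sizes), names(sizes))
  labels[idx] <- sprintf("%s.%d", target, remap[as.character(cl)])
  labels
}

#' Annotate cells with named regions of interest
#'
#' Tags each cell with the first declared ROI polygon containing it
#' (boundary inclusive), or `"none"`. Overlapping ROIs are resolved by
#' declaration order and reported via a message.
#'
#' @param cells A [cell_table()].
#' @param rois Named list of [roi_polygon()]s, in declaration order.
#' @return The cell table with a `region` column.
#' @export
apply_roi_annotation <- function(cells, rois) {
  stopifnot(inherits(cells, "cell_table"), length(names(rois)) == length(rois))
  hits <- vapply(rois, function(r) point_in_polygon(cells$x, cells$y, r),
    logical(nrow(cells)))
  hits <- matrix(hits, nrow = nrow(cells))
  n_hits <- rowSums(hits)
  if (any(n_hits > 1)) {
    message(sprintf(
      "%d cells fall in more than one ROI; resolved by declaration order",
      sum(n_hits > 1)))
  }
  first <- apply(hits, 1L, function(h) if (any(h)) which(h)[1] else NA_integer_)
  cells$region <- ifelse(is.na(first), "none", names(rois)[first])
  cells
}
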