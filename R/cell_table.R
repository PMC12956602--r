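# Tabular I/O for segmented-cell data: the cell table (one row per cell,
# coordinates plus metadata) and the row-aligned feature matrix (marker
# intensities or transcript counts).

# Column names that are metadata, never features. Published in the docs of
# read_cell_table(); any other column of an input table is treated as a
# feature.
RESERVED_CELL_COLUMNS <- c(
  "cell_id", "section_id", "subject_id", "condition", "x", "y",
  "unit", "pixel_size_um", "cell_type", "niche", "region",
  "zone", "distance_um"
)

#' Construct and validate a cell table
#'
#' A cell table holds one row per segmented cell: its centroid coordinates,
#' section/subject/condition metadata, and (as the pipeline progresses)
#' attached phenotype and niche labels. Coordinates are Cartesian with y
#' increasing downward (image convention); only distances are consumed by the
#' analysis stages, so the y direction matters for plotting only.
#'
#' @param df A data.frame with at least `cell_id`, `section_id`, `x`, `y`.
#'   `subject_id` defaults to `section_id`, `condition` to `"H"`, `unit` to
#'   `"um"`.
#' @return A validated `cell_table` (a data.frame subclass).
#' @details Invariants enforced: `(cell_id, section_id)` pairs unique; `x`
#'   and `y` finite and non-negative; `condition` non-empty; if `unit` is
#'   `"pixel"` then `pixel_size_um` must be present and positive.
#' @export
cell_table <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  for (col in c("cell_id", "section_id", "x", "y")) {
    if (!col %in% names(df)) {
      zm_stop(sprintf("mandatory column '%s' is missing", col), "zonemap_schema_error")
    }
  }
  if (!"subject_id" %in% names(df)) df$subject_id <- df$section_id
  if (!"condition" %in% names(df)) df$condition <- "H"
  if (!"unit" %in% names(df)) df$unit <- "um"
  df$cell_id <- as.character(df$cell_id)
  df$section_id <- as.character(df$section_id)
  df$condition <- as.character(df$condition)

  key <- paste(df$cell_id, df$section_id, sep = "\r")
  if (anyDuplicated(key)) {
    zm_stop("duplicated (cell_id, section_id) pairs in cell table", "zonemap_integrity_error")
  }
  if (!all(is.finite(df$x)) || !all(is.finite(df$y))) {
    zm_stop("cell coordinates must be finite", "zonemap_schema_error")
  }
  if (any(df$x < 0) || any(df$y < 0)) {
    zm_stop("cell coordinates must be non-negative", "zonemap_schema_error")
  }
  if (any(!nzchar(df$condition)) || anyNA(df$condition)) {
    zm_stop("condition must be non-empty for every cell", "zonemap_schema_error")
  }
  if (!all(df$unit %in% c("um", "pixel"))) {
    zm_stop("unit must be 'um' or 'pixel'", "zonemap_schema_error")
  }
  if (any(df$unit == "pixel")) {
    if (!"pixel_size_um" %in% names(df) || anyNA(df$pixel_size_um[df$unit == "pixel"])) {
      zm_stop("unit 'pixel' requires a pixel_size_um column", "zonemap_unit_error")
    }
    if (any(df$pixel_size_um[df$unit == "pixel"] <= 0)) {
      zm_stop("pixel_size_um must be positive", "zonemap_unit_error")
    }
  }
  class(df) <- unique(c("cell_table", class(df)))
  df
}

#' Construct a feature matrix
#'
#' A cells-by-features matrix of non-negative values, row-aligned to a cell
#' table. Transcript-count matrices must contain integers.
#'
#' @param values Numeric matrix (cells in rows, features in columns).
#' @param modality `"protein_intensity"` or `"transcript_count"`.
#' @return A `feature_matrix` (a base matrix with a `modality` attribute).
#' @export
feature_matrix <- function(values, modality = c("protein_intensity", "transcript_count")) {
  modality <- match.arg(modality)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (any(!is.finite(values))) zm_stop("feature values must be finite", "zonemap_schema_error")
  if (any(values < 0)) zm_stop("feature values must be non-negative", "zonemap_schema_error")
  if (modality == "transcript_count" && any(values != round(values))) {
    zm_stop("transcript counts must be integers", "zonemap_schema_error")
  }
  if (is.null(colnames(values))) {
    colnames(values) <- paste0("feature_", seq_len(ncol(values)))
  }
  structure(values, modality = modality, class = c("feature_matrix", class(values)))
}

#' Feature-matrix modality
#' @param features A `feature_matrix`.
#' @return `"protein_intensity"` or `"transcript_count"`.
#' @export
modality <- function(features) {
  m <- attr(features, "modality")
  if (is.null(m)) "protein_intensity" else m
}

#' Read a cell table (and optional feature columns) from CSV/TSV
#'
#' Columns outside the reserved metadata set (`cell_id`, `section_id`,
#' `subject_id`, `condition`, `x`, `y`, `unit`, `pixel_size_um`, `cell_type`,
#' `niche`, `region`, `zone`, `distance_um`) are split off into a feature
#' matrix. The modality is inferred: all-integer feature columns are treated
#' as transcript counts, otherwise as protein intensities.
#'
#' @param path Path to the file.
#' @param format `"csv"` or `"tsv"`.
#' @return A list with elements `cells` (a [cell_table()]) and `features`
#'   (a [feature_matrix()] or `NULL` when no feature columns are present).
#' @export
read_cell_table <- function(path, format = c("csv", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) zm_stop(sprintf("file not found: %s", path), "zonemap_io_error")
  df <- if (format == "csv") {
    utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  } else {
    utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  }
  feat_cols <- setdiff(names(df), RESERVED_CELL_COLUMNS)
  feat_cols <- feat_cols[vapply(df[feat_cols], is.numeric, logical(1))]
  cells <- cell_table(df[setdiff(names(df), feat_cols)])
  features <- NULL
  if (length(feat_cols)) {
    vals <- as.matrix(df[feat_cols])
    mod <- if (all(vals == round(vals))) "transcript_count" else "protein_intensity"
    features <- feature_matrix(vals, mod)
  }
  list(cells = cells, features = features)
}

#' Write a cell table (optionally with features) to CSV
#'
#' Inverse of [read_cell_table()]: feature columns are appended after the
#' metadata columns so a round trip recovers both objects.
#'
#' @param cells A [cell_table()].
#' @param path Output path.
#' @param features Optional row-aligned [feature_matrix()].
#' @return `path`, invisibly.
#' @export
write_cell_table <- function(cells, path, features = NULL) {
  df <- as.data.frame(cells)
  if (!is.null(features)) {
    stopifnot(nrow(features) == nrow(df))
    df <- cbind(df, as.data.frame(unclass(features)))
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a transcript-count matrix in MatrixMarket triplet format
#'
#' Follows the common single-cell convention of features in MTX rows and
#' cells in columns; the returned matrix is transposed to cells x features,
#' ordered as in the cells file.
#'
#' @param mtx_path MatrixMarket coordinate file.
#' @param features_path Plain-text file, one feature name per line.
#' @param cells_path Plain-text file, one cell id per line.
#' @return A [feature_matrix()] with modality `"transcript_count"`.
#' @export
read_counts_mtx <- function(mtx_path, features_path, cells_path) {
  for (p in c(mtx_path, features_path, cells_path)) {
    if (!file.exists(p)) zm_stop(sprintf("file not found: %s", p), "zonemap_io_error")
  }
  m <- Matrix::readMM(mtx_path)
  feats <- readLines(features_path)
  feats <- feats[nzchar(feats)]
  cells <- readLines(cells_path)
  cells <- cells[nzchar(cells)]
  if (nrow(m) != length(feats)) {
    zm_stop(sprintf(
      "MTX declares %d features but the feature list has %d entries",
      nrow(m), length(feats)
    ), "zonemap_format_error")
  }
  if (ncol(m) != length(cells)) {
    zm_stop(sprintf(
      "MTX declares %d cells but the cell list has %d entries",
      ncol(m), length(cells)
    ), "zonemap_format_error")
  }
  dense <- t(as.matrix(m))
  dimnames(dense) <- list(cells, feats)
  feature_matrix(dense, "transcript_count")
}

#' Write a transcript-count matrix as MatrixMarket plus feature/cell lists
#'
#' @param features A [feature_matrix()] with modality `"transcript_count"`.
#' @param mtx_path,features_path,cells_path Output paths.
#' @return `mtx_path`, invisibly.
#' @export
write_counts_mtx <- function(features, mtx_path, features_path, cells_path) {
  if (modality(features) != "transcript_count") {
    zm_stop("write_counts_mtx requires a transcript_count matrix", "zonemap_format_error")
  }
  m <- Matrix::Matrix(t(unclass(features)), sparse = TRUE)
  Matrix::writeMM(m, mtx_path)
  writeLines(colnames(features), features_path)
  rn <- rownames(features)
  if (is.null(rn)) rn <- paste0("cell_", seq_len(nrow(features)))
  writeLines(rn, cells_path)
  invisible(mtx_path)
}

#' Convert pixel coordinates to micrometres
#'
#' Multiplies `x` and `y` by `pixel_size_um` for rows recorded in pixel
#' units (the imaging default here is 0.444 um per pixel) and flips the unit
#' flag. Idempotent: tables already in micrometres pass through unchanged.
#'
#' @param cells A [cell_table()].
#' @return The table with coordinates in micrometres and `unit = "um"`.
#' @export
to_um <- function(cells) {
  stopifnot(inherits(cells, "cell_table"))
  px <- cells$unit == "pixel"
  if (any(px)) {
    if (!"pixel_size_um" %in% names(cells) || anyNA(cells$pixel_size_um[px])) {
      zm_stop("unit 'pixel' requires pixel_size_um for conversion", "zonemap_unit_error")
    }
    cells$x[px] <- cells$x[px] * cells$pixel_size_um[px]
    cells$y[px] <- cells$y[px] * cells$pixel_size_um[px]
    cells$unit[px] <- "um"
  }
  cells
}
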