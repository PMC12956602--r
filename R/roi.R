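# Region-of-interest polygons and point-in-polygon cropping, mirroring the
# Xenium-Explorer workflow of drawing a region and exporting its vertex
# coordinates as CSV.

#' Construct a region-of-interest polygon
#'
#' @param vertices Two-column matrix or data.frame of (x, y) vertex
#'   coordinates, ordered along the boundary, in the same unit as the cell
#'   table it will be applied to. At least 3 vertices; the polygon must be
#'   simple (non-self-intersecting) and have non-zero area.
#' @return A `roi_polygon` object.
#' @export
roi_polygon <- function(vertices) {
  v <- as.matrix(vertices)[, 1:2, drop = FALSE]
  storage.mode(v) <- "double"
  colnames(v) <- c("x", "y")
  if (nrow(v) < 3) zm_stop("a polygon needs at least 3 vertices", "zonemap_geometry_error")
  if (any(!is.finite(v))) zm_stop("polygon vertices must be finite", "zonemap_geometry_error")
  # drop a duplicated closing vertex
  if (nrow(v) > 3 && all(v[1, ] == v[nrow(v), ])) v <- v[-nrow(v), , drop = FALSE]
  if (abs(.polygon_area(v)) <= .Machine$double.eps * max(abs(v), 1)) {
    zm_stop("degenerate polygon with zero area", "zonemap_geometry_error")
  }
  if (.self_intersects(v)) zm_stop("polygon is self-intersecting", "zonemap_geometry_error")
  structure(v, class = c("roi_polygon", class(v)))
}

#' Read an ROI polygon from a CSV of vertex rows
#'
#' Expects columns `x` and `y` (header row), one vertex per row in boundary
#' order -- the shape of a region export from an interactive viewer.
#'
#' @param path CSV path.
#' @return A [roi_polygon()].
#' @export
read_roi_csv <- function(path) {
  if (!file.exists(path)) zm_stop(sprintf("file not found: %s", path), "zonemap_io_error")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  nm <- tolower(names(df))
  xi <- match("x", nm); yi <- match("y", nm)
  if (is.na(xi) || is.na(yi)) zm_stop("ROI CSV must have x and y columns", "zonemap_format_error")
  roi_polygon(cbind(df[[xi]], df[[yi]]))
}

# Signed area via the shoelace formula.
.polygon_area <- function(v) {
  n <- nrow(v)
  j <- c(2:n, 1L)
  sum(v[, 1] * v[j, 2] - v[j, 1] * v[, 2]) / 2
}

# Conservative simplicity check: proper crossings between non-adjacent edges.
.self_intersects <- function(v) {
  n <- nrow(v)
  seg <- cbind(v, v[c(2:n, 1L), , drop = FALSE])
  cross <- function(ax, ay, bx, by) ax * by - ay * bx
  for (i in seq_len(n - 2L)) {
    for (j in seq((i + 2L), n)) {
      if (i == 1L && j == n) next # adjacent through the wrap-around
      p1 <- seg[i, 1:2]; p2 <- seg[i, 3:4]
      q1 <- seg[j, 1:2]; q2 <- seg[j, 3:4]
      d1 <- cross(q2[1] - q1[1], q2[2] - q1[2], p1[1] - q1[1], p1[2] - q1[2])
      d2 <- cross(q2[1] - q1[1], q2[2] - q1[2], p2[1] - q1[1], p2[2] - q1[2])
      d3 <- cross(p2[1] - p1[1], p2[2] - p1[2], q1[1] - p1[1], q1[2] - p1[2])
      d4 <- cross(p2[1] - p1[1], p2[2] - p1[2], q2[1] - p1[1], q2[2] - p1[2])
      if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
          ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) {
        return(TRUE)
      }
    }
  }
  FALSE
}

#' Point-in-polygon test (boundary inclusive)
#'
#' Even-odd ray casting with an explicit on-boundary check, vectorised over
#' points. Points lying exactly on an edge or vertex count as inside.
#'
#' @param px,py Point coordinates.
#' @param roi A [roi_polygon()] (or 2-column vertex matrix).
#' @return Logical vector.
#' @export
point_in_polygon <- function(px, py, roi) {
  v <- as.matrix(roi)
  n <- nrow(v)
  vx <- v[, 1]; vy <- v[, 2]
  jx <- vx[c(n, seq_len(n - 1L))]
  jy <- vy[c(n, seq_len(n - 1L))]
  inside <- logical(length(px))
  on_edge <- logical(length(px))
  eps <- 1e-12 * max(abs(v), 1)
  for (e in seq_len(n)) {
    x1 <- jx[e]; y1 <- jy[e]; x2 <- vx[e]; y2 <- vy[e]
    # boundary: collinear and within the segment's bounding box
    cr <- (x2 - x1) * (py - y1) - (y2 - y1) * (px - x1)
    seg_len <- sqrt((x2 - x1)^2 + (y2 - y1)^2)
    on_seg <- abs(cr) <= eps * max(seg_len, 1) &
      px >= pmin(x1, x2) - eps & px <= pmax(x1, x2) + eps &
      py >= pmin(y1, y2) - eps & py <= pmax(y1, y2) + eps
    on_edge <- on_edge | on_seg
    # crossing-number toggle for a rightward ray
    crosses <- ((y1 > py) != (y2 > py)) &
      (px < (x2 - x1) * (py - y1) / (y2 - y1) + x1)
    inside <- xor(inside, crosses & !is.na(crosses))
  }
  inside | on_edge
}

#' Crop a cell table (and aligned features) to a region of interest
#'
#' Retains exactly the cells whose centroid lies inside the polygon,
#' boundary inclusive; feature rows are subset consistently. The ROI must be
#' expressed in the same unit as the cell coordinates.
#'
#' @param cells A [cell_table()].
#' @param features Optional row-aligned [feature_matrix()].
#' @param roi A [roi_polygon()].
#' @return A list with the cropped `cells` and `features` (NULL in, NULL out).
#' @export
crop_roi <- function(cells, features = NULL, roi) {
  stopifnot(inherits(cells, "cell_table"))
  roi <- if (inherits(roi, "roi_polygon")) roi else roi_polygon(roi)
  if (!is.null(features) && nrow(features) != nrow(cells)) {
    zm_stop("features are not row-aligned to the cell table", "zonemap_integrity_error")
  }
  keep <- point_in_polygon(cells$x, cells$y, roi)
  out_cells <- cells[keep, , drop = FALSE]
  class(out_cells) <- class(cells)
  out_features <- if (is.null(features)) NULL else features[keep, , drop = FALSE]
  if (!is.null(out_features)) {
    out_features <- structure(out_features,
      modality = modality(features),
      class = class(features)
    )
  }
  list(cells = out_cells, features = out_features)
}
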