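# Cell-table / MTX reading, ROI cropping, and unit conversion.

write_tmp_csv <- function(df) {
  path <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  utils::write.csv(df, path, row.names = FALSE)
  path
}

test_that("read_cell_table splits metadata from feature columns", {
  base <- data.frame(
    cell_id = c("a", "b", "c"), section_id = "s1", subject_id = "p1",
    condition = "H", x = c(1, 2, 3), y = c(4, 5, 6)
  )
  io <- read_cell_table(write_tmp_csv(base))
  expect_s3_class(io$cells, "cell_table")
  expect_equal(nrow(io$cells), 3)
  expect_null(io$features)

  with_feats <- cbind(base, CD3 = c(0.1, 0.2, 0.3), CD20 = c(1.5, 0, 2))
  io2 <- read_cell_table(write_tmp_csv(with_feats))
  expect_equal(colnames(io2$features), c("CD3", "CD20"))
  expect_equal(modality(io2$features), "protein_intensity")
})

test_that("schema and integrity violations are classed errors", {
  bad <- data.frame(cell_id = "a", section_id = "s1", x = 1) # no y
  expect_error(read_cell_table(write_tmp_csv(bad)), class = "zonemap_schema_error")

  dup <- data.frame(
    cell_id = c("a", "a"), section_id = "s1", x = c(1, 2), y = c(1, 2)
  )
  expect_error(read_cell_table(write_tmp_csv(dup)), class = "zonemap_integrity_error")
  # same id in different sections is fine
  ok <- data.frame(
    cell_id = c("a", "a"), section_id = c("s1", "s2"), x = c(1, 2), y = c(1, 2)
  )
  expect_silent(io <- read_cell_table(write_tmp_csv(ok)))
})

test_that("read_counts_mtx expands coordinates and validates dimensions", {
  dir <- withr::local_tempdir()
  mtx <- file.path(dir, "m.mtx")
  writeLines(c(
    "%%MatrixMarket matrix coordinate integer general",
    "2 2 2", "1 1 3", "2 2 1"
  ), mtx)
  ff <- file.path(dir, "f.txt"); writeLines(c("g1", "g2"), ff)
  cf <- file.path(dir, "c.txt"); writeLines(c("c1", "c2"), cf)
  fm <- read_counts_mtx(mtx, ff, cf)
  expect_equal(unname(unclass(fm)), matrix(c(3, 0, 0, 1), 2, byrow = TRUE),
    ignore_attr = TRUE)
  expect_equal(modality(fm), "transcript_count")
  expect_equal(rownames(fm), c("c1", "c2"))

  # empty entry list -> all zero of declared shape
  writeLines(c("%%MatrixMarket matrix coordinate integer general", "2 2 0"), mtx)
  expect_equal(sum(read_counts_mtx(mtx, ff, cf)), 0)

  # header/cell-list mismatch
  writeLines(c("%%MatrixMarket matrix coordinate integer general", "2 3 0"), mtx)
  expect_error(read_counts_mtx(mtx, ff, cf), class = "zonemap_format_error")
})

test_that("cell table and MTX round trips preserve values", {
  cells <- make_cells(25, seed = 7)
  counts <- feature_matrix(
    matrix(rpois(25 * 3, 2), 25, dimnames = list(NULL, c("g1", "g2", "g3"))),
    "transcript_count"
  )
  path <- withr::local_tempfile(fileext = ".csv")
  write_cell_table(cells, path, features = counts)
  back <- read_cell_table(path)
  expect_equal(back$cells$x, cells$x, tolerance = 1e-9)
  expect_equal(back$cells$y, cells$y, tolerance = 1e-9)
  expect_identical(unname(unclass(back$features)), unname(unclass(counts)))

  dir <- withr::local_tempdir()
  paths <- file.path(dir, c("m.mtx", "f.txt", "c.txt"))
  write_counts_mtx(counts, paths[1], paths[2], paths[3])
  back2 <- read_counts_mtx(paths[1], paths[2], paths[3])
  expect_identical(unname(unclass(back2)), unname(unclass(counts)))
})

test_that("crop_roi keeps inside and boundary cells, drops the rest", {
  sq <- roi_polygon(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)))
  cells <- cell_table(data.frame(
    cell_id = c("in", "out", "edge"), section_id = "s1",
    x = c(0.5, 2, 0), y = c(0.5, 2, 0.5)
  ))
  cropped <- crop_roi(cells, roi = sq)$cells
  expect_setequal(cropped$cell_id, c("in", "edge"))
})

test_that("crop_roi matches an independent point-in-polygon oracle", {
  skip_if_not_installed("mgcv")
  # convex polygon; oracle points kept off the boundary
  poly <- cbind(c(10, 80, 95, 50, 12), c(5, 2, 60, 95, 70))
  cells <- make_cells(500, width = 100, height = 100, seed = 42)
  got <- point_in_polygon(cells$x, cells$y, roi_polygon(poly))
  want <- mgcv::in.out(rbind(poly, poly[1, ]), cbind(cells$x, cells$y))
  expect_identical(got, as.vector(want))
})

test_that("crop_roi with the full bounding box is the identity", {
  cells <- make_cells(100, seed = 3)
  pad <- 1e-6
  bbox <- roi_polygon(cbind(
    c(min(cells$x) - pad, max(cells$x) + pad, max(cells$x) + pad, min(cells$x) - pad),
    c(min(cells$y) - pad, min(cells$y) - pad, max(cells$y) + pad, max(cells$y) + pad)
  ))
  expect_equal(nrow(crop_roi(cells, roi = bbox)$cells), nrow(cells))
})

test_that("degenerate polygons are rejected", {
  expect_error(roi_polygon(cbind(c(0, 1, 2), c(0, 1, 2))), class = "zonemap_geometry_error")
  expect_error(roi_polygon(cbind(c(0, 1), c(0, 1))), class = "zonemap_geometry_error")
})

test_that("to_um converts pixels at the recorded pixel size and is idempotent", {
  px <- cell_table(data.frame(
    cell_id = "a", section_id = "s1", x = 1000, y = 500,
    unit = "pixel", pixel_size_um = 0.444
  ))
  um <- to_um(px)
  expect_equal(um$x, 444)
  expect_equal(um$y, 222)
  expect_equal(um$unit, "um")
  expect_identical(to_um(um), um)

  unit1 <- cell_table(data.frame(
    cell_id = "a", section_id = "s1", x = 7, y = 9,
    unit = "pixel", pixel_size_um = 1
  ))
  conv <- to_um(unit1)
  expect_equal(conv$x, 7)
  expect_equal(conv$unit, "um")

  # missing pixel size cannot be constructed nor converted
  expect_error(
    cell_table(data.frame(cell_id = "a", section_id = "s1", x = 1, y = 1, unit = "pixel")),
    class = "zonemap_unit_error"
  )
})
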