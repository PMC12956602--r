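# Section filtering, nearest-reference distances, proximity summaries, and
# the distance-binned stromal comparison.

cells_with_niches <- function(niches, section = "s1", x = NULL, y = NULL) {
  n <- length(niches)
  cell_table(data.frame(
    cell_id = sprintf("c%04d", seq_len(n)), section_id = section,
    x = if (is.null(x)) seq_len(n) else x,
    y = if (is.null(y)) rep(0, n) else y,
    niche = niches
  ))
}

test_that("filter_sections applies the reference-count threshold exactly", {
  mk <- function(n_tae, sec) {
    data.frame(
      cell_id = sprintf("%s_%04d", sec, seq_len(n_tae + 10)), section_id = sec,
      x = runif(n_tae + 10), y = runif(n_tae + 10),
      niche = c(rep("TAE", n_tae), rep("NeutCT", 10))
    )
  }
  cells <- cell_table(rbind(mk(199, "low"), mk(200, "edge")))
  expect_message(keep <- filter_sections(cells, "TAE", 200), "low")
  expect_equal(keep, "edge")
  expect_setequal(filter_sections(cells, "TAE", 0), c("low", "edge"))
  expect_error(filter_sections(cells, "nope"), class = "zonemap_parameter_error")
  empty <- cells[0, , drop = FALSE]
  class(empty) <- class(cells)
  expect_equal(filter_sections(empty, "TAE"), character())
})

test_that("distance_to_reference is exact on simple geometry", {
  cells <- cells_with_niches(
    c("TAE", "TAE", "immune", "immune"),
    x = c(0, 10, 3, 6), y = c(0, 0, 4, 0)
  )
  d <- distance_to_reference(cells, "TAE")
  expect_equal(d, c(0, 0, 5, 4)) # 3-4-5 triangle; minimum over references
})

test_that("distance_to_reference matches the O(n^2) oracle", {
  cells <- make_cells(300, seed = 23)
  cells$niche <- rep(c("TAE", "immune", "immune"), length.out = 300)
  d <- distance_to_reference(cells, "TAE")
  ref <- cells$niche == "TAE"
  want <- oracle_min_dist(cells$x, cells$y, cells$x[ref], cells$y[ref])
  want[ref] <- 0
  expect_lt(max(abs(d - want)), 1e-9)
})

test_that("distances are invariant under rigid motions", {
  cells <- make_cells(150, seed = 29)
  cells$niche <- rep(c("TAE", "imm"), length.out = 150)
  d0 <- distance_to_reference(cells, "TAE")
  withr::with_seed(3, {
    theta <- runif(1, 0, 2 * pi)
    shift <- runif(2, 50, 100)
  })
  rot <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
  xy <- cbind(cells$x, cells$y) %*% rot
  moved <- as.data.frame(cells)
  moved$x <- xy[, 1] - min(xy[, 1]) + shift[1]
  moved$y <- xy[, 2] - min(xy[, 2]) + shift[2]
  d1 <- distance_to_reference(cell_table(moved), "TAE")
  expect_lt(max(abs(d0 - d1)), 1e-9)
})

test_that("sections without reference cells are skipped with a warning", {
  cells <- cells_with_niches(c("imm", "imm"), section = "noref")
  expect_warning(d <- distance_to_reference(cells, "TAE"),
    class = "zonemap_section_skipped")
  expect_true(all(is.na(d)))
})

test_that("niche_distance_summary counts and averages within the threshold", {
  cells <- cells_with_niches(
    c("TAE", "imm", "imm"),
    x = c(0, 5, 7.5), y = c(0, 0, 0)
  )
  s <- niche_distance_summary(cells, "TAE", "imm", max_distance = 3000)
  expect_equal(s$n_within, 2)
  expect_equal(s$mean_distance, 6.25)

  far <- cells_with_niches(c("TAE", "imm", "imm"), x = c(0, 5, 4000))
  s2 <- niche_distance_summary(far, "TAE", "imm", max_distance = 3000)
  expect_equal(s2$n_within, 1)
  expect_equal(s2$mean_distance, 5)

  # absent niche reported with n = 0 and undefined mean
  s3 <- niche_distance_summary(cells, "TAE", c("imm", "plasma"))
  expect_equal(s3$n_within[s3$niche == "plasma"], 0)
  expect_true(is.na(s3$mean_distance[s3$niche == "plasma"]))

  # infinite threshold counts every immune cell exactly once
  s4 <- niche_distance_summary(far, "TAE", "imm", max_distance = Inf)
  expect_equal(s4$n_within, sum(far$niche == "imm"))
})

test_that("threshold is inclusive and the all-pairs variant is available", {
  cells <- cells_with_niches(c("TAE", "imm"), x = c(0, 3000))
  s <- niche_distance_summary(cells, "TAE", "imm", max_distance = 3000)
  expect_equal(s$n_within, 1)
  two_ref <- cells_with_niches(c("TAE", "TAE", "imm"), x = c(0, 2, 6))
  ap <- niche_distance_summary(two_ref, "TAE", "imm", method = "allpairs")
  expect_equal(ap$mean_distance, 5) # mean of pair distances 6 and 4
})

test_that("stromal bins are half-open, pooled by subject, and fractions exact", {
  cells <- cell_table(data.frame(
    cell_id = sprintf("c%02d", 1:6), section_id = "s1", subject_id = "p1",
    condition = "P",
    x = 0, y = 0, cell_type = c(rep("Fibroblast", 5), "Th"),
    niche = "CT"
  ))
  counts <- feature_matrix(
    matrix(c(1, 2, 3, 0, 5, 9), ncol = 1, dimnames = list(NULL, "CXCL1")),
    "transcript_count"
  )
  distances <- c(10, 20, 99.9, 50, 100, 30) # 5th cell sits exactly at 100
  prof <- bin_stromal_expression(cells, counts, "Fibroblast",
    genes = "CXCL1", distances = distances)
  p1 <- prof[prof$bin == "[0,100)", ]
  expect_equal(p1$n_stromal, 4)
  expect_equal(p1$proportion, 0.75) # 3 of 4 expressing
  p2 <- prof[prof$bin == "[100,500)", ]
  expect_equal(p2$n_stromal, 1) # the boundary cell moved up a bin
  expect_equal(p2$proportion, 1)
  expect_true(is.na(prof$proportion[prof$bin == "[500,1500)"]))
})

test_that("compare_groups reproduces the exact 3v3 case and classifies", {
  prof <- data.frame(
    subject_id = sprintf("p%d", 1:6),
    condition = rep(c("H", "P"), each = 3),
    bin = "[0,100)", gene = "g",
    n_stromal = 10,
    proportion = c(0.1, 0.2, 0.3, 0.7, 0.8, 0.9)
  )
  class(prof) <- c("distance_bin_profile", class(prof))
  out <- compare_groups(prof)
  expect_equal(out$U, 0)
  expect_equal(out$p, 0.1, tolerance = 1e-12)
  expect_equal(out$class, "trend")

  tied <- prof
  tied$proportion <- rep(0.5, 6)
  out2 <- compare_groups(tied)
  expect_equal(out2$p, 1)
  expect_equal(out2$class, "ns")

  small <- prof[-(1:2), ]
  class(small) <- c("distance_bin_profile", class(small))
  expect_equal(compare_groups(small)$class, "untestable")
})

test_that("compare_groups has power against a planted shift", {
  rejections <- vapply(1:100, function(i) {
    withr::with_seed(1000 + i, {
      h <- pmin(pmax(rnorm(8, 0.3, 0.1), 0), 1)
      p <- pmin(pmax(rnorm(10, 0.6, 0.1), 0), 1)
    })
    mann_whitney_u(h, p)$p <= 0.05
  }, logical(1))
  expect_gt(mean(rejections), 0.8)
})
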