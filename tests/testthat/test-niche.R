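# Neighbourhood matrices, niche clustering, merging, and summaries.

test_that("k = 1 neighbourhood is a pure neighbour readout (self excluded)", {
  cells <- cell_table(data.frame(
    cell_id = c("A", "B"), section_id = "s1", x = c(0, 1), y = c(0, 0)
  ))
  feats <- rbind(c(1, 0), c(0, 1))
  colnames(feats) <- c("f1", "f2")
  nb <- build_neighborhood_matrix(cells, feats, k = 1)
  expect_equal(unname(nb), rbind(c(0, 1), c(1, 0)))
})

test_that("identical features give a neighbourhood equal to the features", {
  cells <- make_cells(50, seed = 2)
  feats <- matrix(rep(c(0.3, 0.7), each = 50), 50, dimnames = list(NULL, c("a", "b")))
  nb <- build_neighborhood_matrix(cells, feats, k = 5)
  expect_equal(unname(nb), unname(feats), tolerance = 1e-12)
})

test_that("neighbourhood rows match the exhaustive oracle", {
  cells <- make_cells(200, seed = 13, types = c("T", "B", "Neut"))
  feats <- one_hot_types(cells)
  for (w in c("inverse_distance", "uniform")) {
    nb <- build_neighborhood_matrix(cells, feats, k = 10, weighting = w)
    want <- oracle_neighborhood(cells$x, cells$y, cells$cell_id, feats, 10, w)
    expect_lt(max(abs(nb - want)), 1e-9)
  }
})

test_that("one-hot neighbourhood rows are convex combinations", {
  cells <- make_cells(120, seed = 21, types = c("T", "B", "APC", "Fib"))
  nb <- build_neighborhood_matrix(cells, k = 7)
  expect_true(all(abs(rowSums(nb) - 1) < 1e-9))
  expect_true(all(nb >= 0))
})

test_that("neighbourhoods are permutation equivariant", {
  cells <- make_cells(80, seed = 31, types = c("T", "B"))
  feats <- one_hot_types(cells)
  nb <- build_neighborhood_matrix(cells, feats, k = 6)
  perm <- withr::with_seed(1, sample(80))
  shuffled <- as.data.frame(cells)[perm, ]
  nb_p <- build_neighborhood_matrix(cell_table(shuffled), feats[perm, ], k = 6)
  unshuffled <- nb_p[order(perm), ]
  expect_equal(unname(unshuffled), unname(nb), tolerance = 1e-12)
})

test_that("sections with too few cells are skipped with a warning", {
  cells <- make_cells(30, seed = 5, types = c("T", "B"))
  tiny <- make_cells(3, section = "tiny", seed = 6, types = c("T", "B"))
  both <- cell_table(rbind(as.data.frame(cells), as.data.frame(tiny)))
  expect_warning(nb <- build_neighborhood_matrix(both, k = 5),
    class = "zonemap_section_skipped")
  expect_true(all(is.na(nb[31:33, ])))
  expect_false(anyNA(nb[1:30, ]))
})

test_that("cluster_niches is reproducible and size-orders its labels", {
  cells <- make_cells(300, seed = 17, types = c("T", "B", "Neut"))
  nb <- build_neighborhood_matrix(cells, k = 10)
  c1 <- cluster_niches(nb, 3, seed = 7)
  c2 <- cluster_niches(nb, 3, seed = 7)
  expect_identical(c1$labels, c2$labels)
  tab <- table(c1$labels)
  expect_true(all(diff(as.integer(tab[as.character(1:3)])) <= 0))

  all_one <- cluster_niches(nb, 1, seed = 1)
  expect_equal(unique(all_one$labels), "1")
  expect_error(cluster_niches(nb, 301, seed = 1), class = "zonemap_parameter_error")
})

test_that("merge_niches relabels totally and rejects missing labels", {
  labels <- c("0", "1", "2")
  map <- c("0" = "TAE", "1" = "TAE", "2" = "NeutCT")
  expect_equal(merge_niches(labels, map), c("TAE", "TAE", "NeutCT"))
  expect_equal(merge_niches(labels, c("0" = "0", "1" = "1", "2" = "2")), labels)
  expect_error(merge_niches(c(labels, "3"), map), class = "zonemap_mapping_error")
})

test_that("niche composition reports log10(count + 1)", {
  cells <- cell_table(data.frame(
    cell_id = sprintf("c%02d", 1:12), section_id = "s1",
    x = runif(12), y = runif(12),
    cell_type = c(rep("Th", 9), rep("B", 3)),
    niche = c(rep("T-B-APC", 11), "other")
  ))
  comp <- niche_composition(cells)
  expect_equal(comp$log_counts["Th", "T-B-APC"], 1) # log10(9 + 1)
  expect_equal(comp$log_counts["B", "other"], log10(2))
  expect_equal(comp$counts["Th", "other"], 0)
  expect_equal(comp$log_counts["Th", "other"], 0)
  expect_equal(colSums(comp$counts), c("T-B-APC" = 11, "other" = 1))
})

test_that("niche proportions sum to one within each condition", {
  cells <- cell_table(data.frame(
    cell_id = sprintf("c%02d", 1:10), section_id = "s1",
    condition = c(rep("H", 5), rep("P", 5)),
    x = runif(10), y = runif(10),
    niche = c(rep("A", 3), rep("B", 2), rep("A", 1), rep("B", 4))
  ))
  pr <- niche_proportions(cells)
  expect_equal(pr["H", ], c(A = 0.6, B = 0.4))
  expect_equal(pr["P", ], c(A = 0.2, B = 0.8))
  expect_true(all(abs(rowSums(pr) - 1) < 1e-9))
})

test_that("plasma niche proportion separates conditions in a small cohort", {
  secs <- generate_cohort(3, 3, tissue_config(width_um = 400), seed = 77)
  comb <- combine_sections(secs)
  comb$cells$niche <- comb$truth$zone
  pr <- niche_proportions(comb$cells)
  expect_lt(ifelse("plasma" %in% colnames(pr), pr["H", "plasma"], 0), 0.01)
  expect_gt(pr["P", "plasma"], 0.05)
})

test_that("niche recovery degrades gracefully under compressed zonation", {
  # half-depth layering still separates the planted zones acceptably
  aris <- vapply(1:5, function(s) {
    sec <- generate_section(tissue_config(
      condition = "P", width_um = 1800, zone_scale = 0.5, seed = 300 + s))
    sec$cells$niche <- sec$truth$zone
    nb <- build_neighborhood_matrix(sec$cells, k = 30)
    cl <- cluster_niches(nb, 5, seed = s)
    mclust::adjustedRandIndex(cl$labels, sec$truth$zone)
  }, numeric(1))
  expect_true(all(aris >= 0.6))
})

test_that("niche_sweep reports inertia over the parameter grid", {
  cells <- make_cells(150, seed = 9, types = c("T", "B", "Neut"))
  sweep_tab <- niche_sweep(cells, k_neighbors = c(5, 10), n_clusters = 2:3, seed = 1)
  expect_equal(nrow(sweep_tab), 4)
  expect_true(all(is.finite(sweep_tab$inertia)))
})
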