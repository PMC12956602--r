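# Gaussian-mixture gating, rule-based phenotype assignment, subclustering,
# and ROI annotation.

# intensities whose log1p values follow a two-component normal mixture
mixture_intensities <- function(n, p_high, m_lo = 1, m_hi = 4, s = 0.1, seed = 1) {
  withr::with_seed(seed, {
    z <- ifelse(runif(n) < p_high, rnorm(n, m_hi, s), rnorm(n, m_lo, s))
    expm1(pmax(z, 0))
  })
}

test_that("fitted gate recovers the planted equal-density point", {
  v <- mixture_intensities(2000, 0.5, s = 0.1, seed = 11)
  f <- feature_matrix(matrix(v, ncol = 1, dimnames = list(NULL, "CD3")),
    "protein_intensity")
  g <- fit_gates(f, "CD3", seed = 1)
  planted <- oracle_mixture_gate(0.5, 1, 0.1, 0.5, 4, 0.1)
  expect_lt(abs(g$gates$CD3$gate - planted), 0.1)
  expect_true(g$gates$CD3$means[1] < g$gates$CD3$gate)
  expect_true(g$gates$CD3$gate < g$gates$CD3$means[2])

  # a raw value exactly at the gate rescales to 0.5
  at_gate <- expm1(g$gates$CD3$gate)
  r <- rescale_gated(g, feature_matrix(
    matrix(c(at_gate, 0, max(v)), ncol = 1, dimnames = list(NULL, "CD3")),
    "protein_intensity"))
  expect_equal(unname(r[1, "CD3"]), 0.5, tolerance = 1e-9)
  expect_true(all(r >= 0 & r <= 1))
})

test_that("degenerate markers are rejected", {
  f <- feature_matrix(matrix(5, 100, 1, dimnames = list(NULL, "M")),
    "protein_intensity")
  expect_error(fit_gates(f, "M"), class = "zonemap_gating_error")
  few <- feature_matrix(matrix(c(rep(0, 80), runif(20) + 1), ncol = 1,
    dimnames = list(NULL, "M")), "protein_intensity")
  expect_error(fit_gates(few, "M"), class = "zonemap_gating_error")
})

test_that("gating is scale-equivariant on the log axis for bright markers", {
  # log1p ~ log at these magnitudes, so multiplying intensities by c shifts
  # the fitted gate by log(c) and leaves rescaled values unchanged
  v <- mixture_intensities(3000, 0.4, m_lo = 7, m_hi = 10, s = 0.3, seed = 4)
  f1 <- feature_matrix(matrix(v, ncol = 1, dimnames = list(NULL, "M")),
    "protein_intensity")
  f2 <- feature_matrix(matrix(3 * v, ncol = 1, dimnames = list(NULL, "M")),
    "protein_intensity")
  g1 <- fit_gates(f1, "M", seed = 2)
  g2 <- fit_gates(f2, "M", seed = 2)
  expect_equal(g2$gates$M$gate - g1$gates$M$gate, log(3), tolerance = 1e-3)
  expect_equal(rescale_gated(g2, f2), rescale_gated(g1, f1), tolerance = 1e-3)
})

test_that("recovered positive fractions match planted mixing proportions", {
  for (p in c(0.2, 0.5, 0.8)) {
    v <- mixture_intensities(5000, p, s = 0.25, seed = round(100 * p))
    f <- feature_matrix(matrix(v, ncol = 1, dimnames = list(NULL, "M")),
      "protein_intensity")
    r <- rescale_gated(fit_gates(f, "M", seed = 1), f)
    expect_lt(abs(mean(r > 0.5) - p), 0.03)
  }
})

simple_rules <- phenotype_rules(list(
  list(phenotype = "T", pos = c("CD45", "CD3")),
  list(phenotype = "Th", parent = "T", pos = "CD4"),
  list(phenotype = "Tc", parent = "T", pos = "CD8")
))

test_that("phenotype assignment walks the hierarchy to the deepest match", {
  gated <- rbind(
    c(CD45 = 0.9, CD3 = 0.8, CD4 = 0.7, CD8 = 0.1), # Th
    c(CD45 = 0.9, CD3 = 0.8, CD4 = 0.2, CD8 = 0.2), # stops at T
    c(CD45 = 0.2, CD3 = 0.1, CD4 = 0.1, CD8 = 0.1)  # unknown
  )
  expect_equal(assign_phenotypes(gated, simple_rules), c("Th", "T", "unknown"))
})

test_that("sibling ties break on the mean positive-marker score", {
  gated <- rbind(c(CD45 = 0.9, CD3 = 0.9, CD4 = 0.75, CD8 = 0.60))
  expect_equal(assign_phenotypes(gated, simple_rules), "Th")
  gated2 <- rbind(c(CD45 = 0.9, CD3 = 0.9, CD4 = 0.60, CD8 = 0.75))
  expect_equal(assign_phenotypes(gated2, simple_rules), "Tc")
})

test_that("assignment is total, deterministic, and validates markers", {
  withr::with_seed(8, {
    gated <- matrix(runif(200 * 4), 200,
      dimnames = list(NULL, c("CD45", "CD3", "CD4", "CD8")))
  })
  l1 <- assign_phenotypes(gated, simple_rules)
  l2 <- assign_phenotypes(gated, simple_rules)
  expect_identical(l1, l2)
  expect_length(l1, 200)
  expect_false(anyNA(l1))

  bad <- phenotype_rules(list(list(phenotype = "X", pos = "NOPE")))
  expect_error(assign_phenotypes(gated, bad), class = "zonemap_schema_error")
})

test_that("rules must declare parents before children", {
  expect_error(
    phenotype_rules(list(
      list(phenotype = "Th", parent = "T", pos = "CD4"),
      list(phenotype = "T", pos = "CD3")
    )),
    class = "zonemap_schema_error"
  )
})

test_that("anypos and neg modifiers behave as documented", {
  rules <- phenotype_rules(list(
    list(phenotype = "Epi", anypos = c("PanCK", "CK19"), neg = "CD45")
  ))
  gated <- rbind(
    c(PanCK = 0.9, CK19 = 0.1, CD45 = 0.1), # anypos satisfied
    c(PanCK = 0.1, CK19 = 0.1, CD45 = 0.1), # no anypos hit
    c(PanCK = 0.9, CK19 = 0.9, CD45 = 0.9)  # neg violated
  )
  expect_equal(assign_phenotypes(gated, rules), c("Epi", "unknown", "unknown"))
})

test_that("subcluster splits only the target phenotype, ordered by size", {
  withr::with_seed(5, {
    blob1 <- matrix(rnorm(60 * 2, 0.2, 0.02), 60)
    blob2 <- matrix(rnorm(40 * 2, 0.8, 0.02), 40)
    other <- matrix(runif(30 * 2), 30)
  })
  gated <- rbind(blob1, blob2, other)
  colnames(gated) <- c("M1", "M2")
  labels <- c(rep("T", 100), rep("B", 30))
  out <- subcluster(gated, labels, "T", k = 2, seed = 1)
  expect_equal(out[101:130], rep("B", 30))
  # larger blob gets suffix .1; split matches planted membership exactly
  expect_equal(out[1:60], rep("T.1", 60))
  expect_equal(out[61:100], rep("T.2", 40))

  one <- subcluster(gated, labels, "B", k = 1)
  expect_equal(unique(one[101:130]), "B.1")
  expect_error(subcluster(gated, labels, "B", k = 40),
    class = "zonemap_clustering_error")
})

test_that("ROI annotation uses declaration order and tags outsiders none", {
  cells <- cell_table(data.frame(
    cell_id = c("a", "b", "c"), section_id = "s1",
    x = c(1, 3, 9), y = c(1, 1, 9)
  ))
  rois <- list(
    OE = roi_polygon(cbind(c(0, 4, 4, 0), c(0, 0, 2, 2))),
    TAE = roi_polygon(cbind(c(2, 6, 6, 2), c(0, 0, 2, 2)))
  )
  expect_message(out <- apply_roi_annotation(cells, rois), "more than one ROI")
  expect_equal(out$region, c("OE", "OE", "none"))
})
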