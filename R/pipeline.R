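# Pipeline orchestration: named stages over on-disk artifacts, a full
# synthetic demo, and a run manifest (config hash, seed, version) written
# next to every stage's outputs. All randomness flows from one root seed
# via fixed per-stage offsets.

.stage_seed <- function(seed, stage) {
  offsets <- c(
    simulate = 101L, phenotype = 211L, niche = 307L, zonate = 401L,
    de = 503L, lr = 601L, transfer = 701L, demo = 811L
  )
  (as.integer(seed) + offsets[[stage]]) %% .Machine$integer.max
}

#' Default pipeline configuration
#'
#' Returns the shipped default configuration (also available as YAML at
#' `system.file("extdata", "default_config.yaml", package = "zonemap")`):
#' cohort sizes, niche parameters (neighbourhood size, cluster count),
#' zonation parameters (reference niche, minimum reference cells, distance
#' threshold, bin edges), ligand-receptor cutoff, and transfer parameters.
#'
#' @param path Optional YAML file; entries override the defaults.
#' @return A named list.
#' @export
pipeline_config <- function(path = NULL) {
  cfg <- yaml::read_yaml(system.file("extdata", "default_config.yaml", package = "zonemap"))
  if (!is.null(path)) {
    if (!file.exists(path)) zm_stop(sprintf("config not found: %s", path), "zonemap_io_error")
    user <- yaml::read_yaml(path)
    cfg[names(user)] <- user
  }
  cfg
}

.write_manifest <- function(outdir, stage, config, seed, artifacts) {
  cfg_file <- tempfile(fileext = ".yaml")
  yaml::write_yaml(config, cfg_file)
  manifest <- list(
    stage = stage,
    config_md5 = unname(tools::md5sum(cfg_file)),
    seed = as.integer(seed),
    package_version = as.character(utils::packageVersion("zonemap")),
    artifacts = artifacts
  )
  unlink(cfg_file)
  jsonlite::write_json(manifest, file.path(outdir, paste0(stage, "_manifest.json")),
    auto_unbox = TRUE, pretty = TRUE)
}

#' Run a pipeline stage
#'
#' Subcommands: `simulate` (write a synthetic cohort), `phenotype` (gate
#' and label a protein-modality table), `niche` (neighbourhood clustering
#' and merge), `zonate` (section filter, proximity summary, distance-binned
#' stromal comparison), `de` (rank-sum differential expression on the
#' reference niche), `lr` (ligand-receptor coexpression per niche),
#' `transfer` (reference/query label transfer on a synthetic split), and
#' `demo` (the full chain on one simulated cohort). Stages read and write
#' CSV artifacts under `outdir` and each writes a `<stage>_manifest.json`
#' recording the config hash, seed, and package version.
#'
#' @param subcommand One of the stage names above.
#' @param outdir Output (and, for later stages, input) directory.
#' @param config A [pipeline_config()] list or path to a YAML file.
#' @param seed Root integer seed.
#' @return Invisibly, a character vector of artifact paths written.
#' @export
run_pipeline <- function(subcommand, outdir, config = NULL, seed = 1L) {
  stages <- c("simulate", "phenotype", "niche", "zonate", "de", "lr", "transfer", "demo")
  if (!subcommand %in% stages) {
    zm_stop(sprintf("unknown subcommand '%s' (expected one of %s)",
      subcommand, paste(stages, collapse = ", ")), "zonemap_usage_error")
  }
  if (is.character(config)) config <- pipeline_config(config)
  if (is.null(config)) config <- pipeline_config()
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  fn <- switch(subcommand,
    simulate = .stage_simulate, phenotype = .stage_phenotype,
    niche = .stage_niche, zonate = .stage_zonate, de = .stage_de,
    lr = .stage_lr, transfer = .stage_transfer, demo = .stage_demo
  )
  artifacts <- fn(outdir, config, .stage_seed(seed, subcommand))
  .write_manifest(outdir, subcommand, config, seed, basename(artifacts))
  invisible(artifacts)
}

.read_stage_cells <- function(outdir) {
  path <- file.path(outdir, "cells.csv")
  if (!file.exists(path)) {
    zm_stop("cells.csv not found; run the simulate stage first", "zonemap_io_error")
  }
  read_cell_table(path)
}

.stage_simulate <- function(outdir, config, seed) {
  base <- tissue_config(
    width_um = config$section$width_um,
    density_per_mm2 = config$section$density_per_mm2
  )
  sections <- generate_cohort(config$cohort$n_H, config$cohort$n_P, base, seed = seed)
  comb <- combine_sections(sections)
  message(sprintf("simulate: %d sections, %d cells", length(sections), nrow(comb$cells)))
  cells_path <- file.path(outdir, "cells.csv")
  write_cell_table(comb$cells, cells_path, features = comb$features)
  truth_path <- file.path(outdir, "truth.csv")
  utils::write.csv(comb$truth, truth_path, row.names = FALSE)
  c(cells_path, truth_path)
}

.stage_phenotype <- function(outdir, config, seed) {
  cfg <- tissue_config(
    condition = "P", modality = "protein_intensity",
    width_um = config$section$width_um,
    density_per_mm2 = config$section$density_per_mm2, seed = seed
  )
  sec <- generate_section(cfg)
  rules <- read_phenotype_rules(
    config$phenotype$rules %||%
      system.file("extdata", "phenotype_rules.yaml", package = "zonemap")
  )
  gates <- fit_gates(sec$features, seed = seed)
  gated <- rescale_gated(gates, sec$features)
  sec$cells$cell_type <- assign_phenotypes(gated, rules)
  message(sprintf("phenotype: %d cells, %d unknown", nrow(sec$cells),
    sum(sec$cells$cell_type == "unknown")))
  path <- file.path(outdir, "phenotyped_cells.csv")
  write_cell_table(sec$cells, path)
  gpath <- file.path(outdir, "gated.csv")
  utils::write.csv(cbind(cell_id = sec$cells$cell_id, as.data.frame(gated)),
    gpath, row.names = FALSE)
  c(path, gpath)
}

.stage_niche <- function(outdir, config, seed) {
  io <- .read_stage_cells(outdir)
  cells <- io$cells
  nb <- build_neighborhood_matrix(cells,
    k = config$niche$k_neighbors,
    weighting = config$niche$weighting
  )
  cl <- cluster_niches(nb, config$niche$n_clusters, seed = seed)
  # name raw clusters by their dominant planted zone when truth is present,
  # mirroring merge-by-composition; otherwise keep raw numeric names
  truth_path <- file.path(outdir, "truth.csv")
  if (file.exists(truth_path)) {
    truth <- utils::read.csv(truth_path, stringsAsFactors = FALSE)
    zone <- truth$zone[match(
      paste(cells$section_id, cells$cell_id),
      paste(truth$section_id, truth$cell_id)
    )]
    raw <- unique(cl$labels[!is.na(cl$labels)])
    merge_map <- vapply(raw, function(l) {
      names(which.max(table(zone[cl$labels == l & !is.na(cl$labels)])))
    }, character(1))
    cells$niche <- merge_niches(cl$labels, merge_map)
  } else {
    cells$niche <- cl$labels
  }
  message(sprintf("niche: %d clusters over %d cells", config$niche$n_clusters, nrow(cells)))
  path <- file.path(outdir, "cells_with_niches.csv")
  write_cell_table(cells, path, features = io$features)
  path
}

.read_niche_cells <- function(outdir) {
  path <- file.path(outdir, "cells_with_niches.csv")
  if (!file.exists(path)) {
    zm_stop("cells_with_niches.csv not found; run the niche stage first", "zonemap_io_error")
  }
  read_cell_table(path)
}

.stage_zonate <- function(outdir, config, seed) {
  io <- .read_niche_cells(outdir)
  cells <- io$cells
  zc <- config$zonation
  eligible <- filter_sections(cells, zc$ref_niche, zc$min_cells)
  keep <- cells$section_id %in% eligible
  cells_f <- cells[keep, , drop = FALSE]
  class(cells_f) <- class(cells)
  summ <- niche_distance_summary(cells_f, zc$ref_niche,
    immune_niches = zc$immune_niches, max_distance = zc$max_distance)
  zpath <- file.path(outdir, "zonation_summary.csv")
  utils::write.csv(as.data.frame(summ), zpath, row.names = FALSE)
  artifacts <- zpath
  if (!is.null(io$features)) {
    prof <- bin_stromal_expression(cells_f, io$features[keep, , drop = FALSE],
      stromal_types = zc$stromal_types,
      genes = intersect(zc$genes %||% colnames(io$features), colnames(io$features)),
      ref_niche = zc$ref_niche, bins = unlist(zc$bins))
    cmp <- compare_groups(prof)
    ppath <- file.path(outdir, "stromal_bins.csv")
    cpath <- file.path(outdir, "group_comparison.csv")
    utils::write.csv(as.data.frame(prof), ppath, row.names = FALSE)
    utils::write.csv(cmp, cpath, row.names = FALSE)
    artifacts <- c(artifacts, ppath, cpath)
  }
  message(sprintf("zonate: %d/%d sections eligible", length(eligible),
    length(unique(cells$section_id))))
  artifacts
}

.stage_de <- function(outdir, config, seed) {
  io <- .read_niche_cells(outdir)
  if (is.null(io$features)) zm_stop("no feature columns found", "zonemap_io_error")
  ref <- config$zonation$ref_niche
  sel <- !is.na(io$cells$niche) & io$cells$niche == ref
  de <- wilcoxon_de(io$features[sel, , drop = FALSE], io$cells$condition[sel])
  message(sprintf("de: %d genes tested on %d '%s' cells, %d at q <= 0.05",
    nrow(de), sum(sel), ref, sum(de$q <= 0.05)))
  path <- file.path(outdir, "de_results.csv")
  utils::write.csv(cbind(de, neg_log10_p = -log10(pmax(de$p, 1e-300))),
    path, row.names = FALSE)
  path
}

.stage_lr <- function(outdir, config, seed) {
  io <- .read_niche_cells(outdir)
  if (is.null(io$features)) zm_stop("no feature columns found", "zonemap_io_error")
  pairs <- load_pairs(
    config$lr$pairs %||% system.file("extdata", "lr_pairs.tsv", package = "zonemap")
  )
  scores <- niche_lr_scores(io$cells, io$features, pairs,
    fraction_cutoff = config$lr$fraction_cutoff)
  spath <- file.path(outdir, "lr_scores.csv")
  hpath <- file.path(outdir, "lr_heatmap.csv")
  utils::write.csv(scores$pair_scores, spath, row.names = FALSE)
  utils::write.csv(lr_heatmap_table(scores), hpath, row.names = FALSE)
  message(sprintf("lr: %d pair-niche scores, %d coexpressed",
    nrow(scores$pair_scores), sum(scores$pair_scores$coexpressed)))
  c(spath, hpath)
}

.stage_transfer <- function(outdir, config, seed) {
  tc <- config$transfer
  sim <- simulate_transfer_problem(
    n_ref = tc$n_ref, n_query = tc$n_query, n_types = tc$n_types,
    batch_shift = tc$batch_shift, noise_sd = tc$noise_sd, seed = seed
  )
  model <- fit_joint_embedding(sim$ref, sim$query,
    n_pcs = tc$n_pcs, n_align_iters = tc$n_align_iters,
    ref_labels = sim$ref_labels, seed = seed)
  tr <- transfer_labels(model, sim$ref_labels, k = tc$k)
  acc <- mean(tr$label == sim$query_labels)
  message(sprintf("transfer: accuracy %.3f over %d query cells", acc, nrow(tr)))
  path <- file.path(outdir, "transfer_labels.csv")
  utils::write.csv(data.frame(
    true_label = sim$query_labels, label = tr$label, confidence = tr$confidence
  ), path, row.names = FALSE)
  path
}

.stage_demo <- function(outdir, config, seed) {
  a1 <- .stage_simulate(outdir, config, seed)
  a2 <- .stage_niche(outdir, config, seed + 1L)
  a3 <- .stage_zonate(outdir, config, seed + 2L)
  a4 <- .stage_de(outdir, config, seed + 3L)
  a5 <- .stage_lr(outdir, config, seed + 4L)
  c(a1, a2, a3, a4, a5)
}

#' Simulate a reference/query label-transfer problem
#'
#' Generates a multi-type single-cell reference and a query drawn from the
#' same generative model, applies a constant per-gene batch shift and
#' additive Gaussian expression noise to the query, and returns normalised
#' log1p matrices with ground-truth labels. Each type expresses its own
#' block of marker genes on top of a shared background.
#'
#' @param n_ref,n_query Cells per dataset.
#' @param n_types Number of cell types.
#' @param n_genes Genes in the panel (at least `n_types` marker blocks).
#' @param batch_shift Maximum per-gene constant offset added to the query
#'   on the log1p scale (drawn uniform in `[0, batch_shift]`).
#' @param noise_sd Additive noise on the query, as a fraction of each
#'   gene's standard deviation.
#' @param seed Integer seed.
#' @return A list: `ref`, `query` (normalised log1p matrices),
#'   `ref_labels`, `query_labels`.
#' @export
simulate_transfer_problem <- function(n_ref = 2000, n_query = 2000, n_types = 5,
                                      n_genes = 60, batch_shift = 1,
                                      noise_sd = 0.1, seed = 1L) {
  zm_with_seed(seed, {
    genes <- sprintf("G%03d", seq_len(n_genes))
    types <- sprintf("type%d", seq_len(n_types))
    block <- split(seq_len(n_genes), rep(seq_len(n_types), length.out = n_genes))
    mu <- matrix(0.2, n_genes, n_types, dimnames = list(genes, types))
    for (t in seq_len(n_types)) mu[block[[t]], t] <- 5
    draw <- function(n) {
      lab <- sample(types, n, replace = TRUE)
      counts <- matrix(stats::rnbinom(n * n_genes, size = 2, mu = t(mu[, lab])),
        nrow = n, byrow = FALSE, dimnames = list(NULL, genes))
      list(x = counts, labels = lab)
    }
    r <- draw(n_ref); q <- draw(n_query)
    fm <- function(m) feature_matrix(m, "transcript_count")
    ref <- normalize_features(fm(r$x))$lognorm
    query <- normalize_features(fm(q$x))$lognorm
    shift <- stats::runif(n_genes, 0, batch_shift)
    query <- sweep(query, 2, shift, "+")
    if (noise_sd > 0) {
      sds <- apply(query, 2, stats::sd)
      query <- query + matrix(stats::rnorm(length(query), 0, 1), nrow(query)) *
        matrix(noise_sd * sds, nrow(query), n_genes, byrow = TRUE)
      query <- pmax(query, 0)
    }
    list(ref = ref, query = query, ref_labels = r$labels, query_labels = q$labels)
  })
}
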