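# Synthetic layered-mucosa generator. Virtual sections reproduce the
# architecture of the gingival barrier: an external oral epithelium (OE)
# band, a tooth-associated epithelium (TAE) band, and connective-tissue
# zones stacked by distance from the TAE -- a neutrophil band at 0-100 um, a
# T/B/antigen-presenting-cell aggregate at 100-500 um, and (in disease only)
# a plasma-cell zone at 500-1500 um. Stromal cells carry distance-graded
# gene programs and disease multiplies neutrophil density and proximal gene
# means, so every downstream stage has a planted ground truth.

# Default negative-binomial mean matrix (genes x cell types). Dispersion is
# shared (theta). Marker structure: each type expresses its canonical
# markers; gradient genes live in the stromal types and are modulated by
# zone; ligand-receptor partners are planted in TAE epithelium (CSF3, SAA1)
# and neutrophils (CSF3R, FPR1). Housekeeping genes are flat across zones
# and conditions and serve as negative controls.
.default_expression_model <- function() {
  types <- c(
    "Epi.OE", "Epi.TAE", "Neutrophil", "Th", "B", "APC",
    "Plasma", "Fibroblast", "Endothelial"
  )
  genes <- c(
    "KRT5", "CNFN", "KRT19", "ODAM", "LAMC2",
    "FCGR3B", "CSF3R", "FPR1",
    "TRAC", "CD4", "MS4A1", "BANK1", "HLA-DRB5", "CD14", "CCR7", "CXCR4",
    "MZB1", "PRDM1",
    "COL1A1", "PDGFRA", "PECAM1",
    "CSF3",
    "SELE", "ICAM1", "CXCL1", "SAA1",
    "CCL19", "HLA-DMB",
    "CXCL12", "COL16A1",
    "ACTB", "GAPDH", "B2M", "RPL13A", "EEF1A1", "TUBB"
  )
  mu <- matrix(0.02, length(genes), length(types), dimnames = list(genes, types))
  set_mu <- function(gene, type, value) mu[gene, type] <<- value
  set_mu("KRT5", "Epi.OE", 3); set_mu("CNFN", "Epi.OE", 2)
  set_mu("KRT19", "Epi.TAE", 3); set_mu("ODAM", "Epi.TAE", 2.5)
  set_mu("LAMC2", "Epi.TAE", 1.5)
  set_mu("FCGR3B", "Neutrophil", 3)
  set_mu("CSF3R", "Neutrophil", 3); set_mu("FPR1", "Neutrophil", 2.5)
  set_mu("TRAC", "Th", 3); set_mu("CD4", "Th", 2)
  set_mu("CD4", "APC", 0.5)
  set_mu("MS4A1", "B", 3); set_mu("BANK1", "B", 2.5)
  set_mu("HLA-DRB5", "B", 1.5); set_mu("HLA-DRB5", "APC", 3)
  set_mu("CD14", "APC", 2)
  set_mu("CCR7", "APC", 1.2); set_mu("CCR7", "Th", 0.8)
  set_mu("CXCR4", "Th", 0.8); set_mu("CXCR4", "B", 0.8); set_mu("CXCR4", "Plasma", 1)
  set_mu("MZB1", "Plasma", 4); set_mu("PRDM1", "Plasma", 2.5)
  set_mu("COL1A1", "Fibroblast", 4); set_mu("PDGFRA", "Fibroblast", 2)
  set_mu("PECAM1", "Endothelial", 3)
  set_mu("CSF3", "Epi.TAE", 2)
  set_mu("SAA1", "Epi.TAE", 2)
  # gradient genes: base stromal mean, modulated per zone bin below
  for (g in c("SELE", "ICAM1", "CXCL1", "SAA1")) {
    mu[g, c("Fibroblast", "Endothelial")] <- 0.45
  }
  for (g in c("CCL19", "HLA-DMB")) mu[g, c("Fibroblast", "Endothelial")] <- 0.5
  for (g in c("CXCL12", "COL16A1")) mu[g, c("Fibroblast", "Endothelial")] <- 0.5
  mu[c("ACTB", "GAPDH", "B2M", "RPL13A", "EEF1A1", "TUBB"), ] <- 0.5
  list(mu = mu, theta = 2, types = types, genes = genes)
}

# Log-normal intensity model for the protein modality: meanlog per
# (marker, type); positive markers sit ~3 log-units above negatives.
.default_intensity_model <- function() {
  types <- c(
    "Epi.OE", "Epi.TAE", "Neutrophil", "Th", "B", "APC",
    "Plasma", "Fibroblast", "Endothelial"
  )
  markers <- c(
    "CD45", "CD3", "CD4", "CD8", "CD20", "CD138", "MPO",
    "HLADR", "VIM", "CD31", "CK19", "SMA", "PanCK"
  )
  lo <- log(80); hi <- log(2000)
  m <- matrix(lo, length(markers), length(types), dimnames = list(markers, types))
  pos <- list(
    Epi.OE = c("PanCK", "CD138"),
    Epi.TAE = c("PanCK", "CK19"),
    Neutrophil = c("CD45", "MPO"),
    Th = c("CD45", "CD3", "CD4"),
    B = c("CD45", "CD20", "HLADR"),
    APC = c("CD45", "HLADR"),
    Plasma = c("CD45", "CD138"),
    Fibroblast = c("VIM", "SMA"),
    Endothelial = c("VIM", "CD31")
  )
  for (ty in names(pos)) m[pos[[ty]], ty] <- hi
  list(meanlog = m, sdlog = 0.4, types = types, markers = markers)
}

.default_zones <- function(condition) {
  # Zone intervals are distances from the lower edge of the TAE band, in um.
  # density_mult scales the baseline cellularity: inflammatory zones are at
  # baseline, the deep fibrous connective tissue is cell-poor.
  zones <- data.frame(
    zone = c("NeutCT", "T-B-APC", if (condition == "P") "plasma" else "FibCT"),
    dist_lo = c(0, 100, 500),
    dist_hi = c(100, 500, 1500),
    density_mult = c(1, 1, 0.4),
    stringsAsFactors = FALSE
  )
  comp <- list(
    NeutCT = c(Neutrophil = 0.60, Fibroblast = 0.25, Endothelial = 0.10, Th = 0.05),
    `T-B-APC` = c(
      Th = 0.35, B = 0.25, APC = 0.15, Fibroblast = 0.15,
      Endothelial = 0.10
    ),
    plasma = c(
      Plasma = 0.55, Th = 0.10, B = 0.05, Fibroblast = 0.20,
      Endothelial = 0.10
    ),
    FibCT = c(Fibroblast = 0.70, Endothelial = 0.20, Th = 0.10)
  )
  list(zones = zones, composition = comp[zones$zone])
}

# Per-zone-bin multipliers for the planted gradient genes (rows follow the
# three distance bins 0-100 / 100-500 / 500-1500 um).
.default_gradients <- function() {
  data.frame(
    gene = c(
      "SELE", "ICAM1", "CXCL1", "SAA1",
      "CCL19", "HLA-DMB", "CXCL12", "COL16A1"
    ),
    program = c(rep("proximal", 4), rep("intermediate", 2), rep("distal", 2)),
    m1 = c(rep(1.00, 4), rep(0.20, 2), rep(0.10, 2)),
    m2 = c(rep(0.25, 4), rep(1.00, 2), rep(0.30, 2)),
    m3 = c(rep(0.08, 4), rep(0.30, 2), rep(1.00, 2)),
    stringsAsFactors = FALSE
  )
}

#' Configuration of a synthetic gingival section
#'
#' Captures the planted architecture of one virtual section: band geometry
#' (an OE band, a TAE band, and connective-tissue zones defined by distance
#' intervals from the TAE), cell density, per-zone cell-type composition,
#' the expression model, distance-graded gene programs, and the disease
#' effects applied when `condition = "P"` (neutrophil-band density
#' multiplied by `f_neut`, proximal stromal gene means multiplied by
#' `f_prox`, and the deep plasma zone enabled).
#'
#' @param condition `"H"` (health) or `"P"` (periodontitis).
#' @param width_um Section width in micrometres.
#' @param density_per_mm2 Baseline cell density (cells per mm^2) of the
#'   connective-tissue bands; epithelial bands are denser by
#'   `epi_density_mult` and the deep zone is cell-poor (see the zone
#'   table's `density_mult`).
#' @param epi_density_mult Density multiplier of the two epithelial bands
#'   (stratified epithelium is considerably more cellular than stroma).
#' @param oe_band_um,tae_band_um Thickness of the two epithelial bands (um).
#' @param f_neut Disease multiplier on neutrophil-band density.
#' @param f_prox Disease multiplier on proximal stromal gene means.
#' @param modality `"transcript_count"` or `"protein_intensity"`.
#' @param zone_scale Multiplier on all band thicknesses and zone depth
#'   intervals (1 = the default geometry; 0.5 compresses the layering to
#'   half its depth, used to probe recovery under tighter zonation).
#' @param section_id,subject_id Identifiers stamped on the generated cells.
#' @param seed Integer seed; identical configs generate identical sections.
#' @return A `tissue_config` list.
#' @export
tissue_config <- function(condition = c("H", "P"),
                          width_um = 1000,
                          density_per_mm2 = 3000,
                          epi_density_mult = 2,
                          oe_band_um = 100,
                          tae_band_um = 100,
                          f_neut = 3,
                          f_prox = 2,
                          modality = c("transcript_count", "protein_intensity"),
                          zone_scale = 1,
                          section_id = NULL,
                          subject_id = NULL,
                          seed = 1L) {
  condition <- match.arg(condition)
  modality <- match.arg(modality)
  if (width_um <= 0 || density_per_mm2 <= 0) {
    zm_stop("width and density must be positive", "zonemap_parameter_error")
  }
  if (f_neut <= 0 || f_prox <= 0) {
    zm_stop("condition-effect multipliers must be positive", "zonemap_parameter_error")
  }
  zd <- .default_zones(condition)
  if (zone_scale <= 0) zm_stop("zone_scale must be positive", "zonemap_parameter_error")
  zd$zones$dist_lo <- zd$zones$dist_lo * zone_scale
  zd$zones$dist_hi <- zd$zones$dist_hi * zone_scale
  oe_band_um <- oe_band_um * zone_scale
  tae_band_um <- tae_band_um * zone_scale
  comp_sums <- vapply(zd$composition, sum, numeric(1))
  stopifnot(all(abs(comp_sums - 1) < 1e-9))
  if (is.null(section_id)) section_id <- paste0(condition, "_s1")
  if (is.null(subject_id)) subject_id <- sub("_s[0-9]+$", "", section_id)
  structure(list(
    condition = condition,
    width_um = width_um,
    density_per_mm2 = density_per_mm2,
    epi_density_mult = epi_density_mult,
    oe_band_um = oe_band_um,
    tae_band_um = tae_band_um,
    zones = zd$zones,
    composition = zd$composition,
    gradients = .default_gradients(),
    f_neut = f_neut,
    f_prox = f_prox,
    modality = modality,
    zone_scale = zone_scale,
    expression = if (modality == "transcript_count") {
      .default_expression_model()
    } else {
      .default_intensity_model()
    },
    section_id = section_id,
    subject_id = subject_id,
    seed = as.integer(seed)
  ), class = "tissue_config")
}

# Uniform placement of a Poisson number of cells inside a horizontal band.
.place_band <- function(n, width, y_lo, y_hi) {
  data.frame(x = stats::runif(n, 0, width), y = stats::runif(n, y_lo, y_hi))
}

#' Generate one synthetic section
#'
#' Cells are placed by a homogeneous spatial Poisson process within each
#' band. The TAE band spans depths `[oe_band_um, oe_band_um + tae_band_um)`;
#' connective-tissue zone intervals are offsets from the lower TAE edge.
#' Expression is sampled from the per-type model (negative binomial for
#' counts, log-normal for intensities) with zone-dependent gradient effects
#' applied to stromal cells, and disease effects when `condition = "P"`.
#'
#' @param config A [tissue_config()].
#' @param density_scale Multiplier on all band densities (used by
#'   [generate_cohort()] for subject-level jitter).
#' @return A list with `cells` (a [cell_table()] whose `cell_type` column
#'   carries the true type), `features` (a [feature_matrix()]), and `truth`
#'   (data.frame of per-cell true zone, type, and distance to the TAE band,
#'   with the planted gradient table and ligand-receptor pairs as
#'   attributes).
#' @export
generate_section <- function(config, density_scale = 1) {
  stopifnot(inherits(config, "tissue_config"))
  zones <- config$zones
  tae_bottom <- config$oe_band_um + config$tae_band_um
  if (any(zones$dist_hi <= zones$dist_lo)) {
    zm_stop("zone intervals must have positive depth", "zonemap_geometry_error")
  }
  zm_with_seed(config$seed, {
    dens <- config$density_per_mm2 * density_scale
    width <- config$width_um
    area_mm2 <- function(depth_um) (width / 1000) * (depth_um / 1000)

    bands <- list()
    # epithelial bands
    epi_mult <- config$epi_density_mult %||% 2
    n_oe <- stats::rpois(1, dens * epi_mult * area_mm2(config$oe_band_um))
    bands$OE <- cbind(
      .place_band(n_oe, width, 0, config$oe_band_um),
      zone = "OE"
    )
    n_tae <- stats::rpois(1, dens * epi_mult * area_mm2(config$tae_band_um))
    bands$TAE <- cbind(
      .place_band(n_tae, width, config$oe_band_um, tae_bottom),
      zone = "TAE"
    )
    for (i in seq_len(nrow(zones))) {
      z <- zones[i, ]
      zdens <- dens * (z$density_mult %||% 1)
      if (config$condition == "P" && z$zone == "NeutCT") zdens <- zdens * config$f_neut
      n <- stats::rpois(1, zdens * area_mm2(z$dist_hi - z$dist_lo))
      bands[[z$zone]] <- cbind(
        .place_band(n, width, tae_bottom + z$dist_lo, tae_bottom + z$dist_hi),
        zone = z$zone
      )
    }
    pos <- do.call(rbind, bands)
    n_cells <- nrow(pos)

    # cell types per zone composition
    comp <- c(
      list(
        OE = c(Epi.OE = 0.95, Th = 0.05),
        TAE = c(Epi.TAE = 0.80, Neutrophil = 0.20)
      ),
      config$composition
    )
    cell_type <- character(n_cells)
    for (zn in unique(pos$zone)) {
      idx <- which(pos$zone == zn)
      p <- comp[[zn]]
      cell_type[idx] <- sample(names(p), length(idx), replace = TRUE, prob = p)
    }

    dist_tae <- ifelse(
      pos$zone == "TAE", 0,
      ifelse(pos$y < config$oe_band_um, config$oe_band_um - pos$y, pos$y - tae_bottom)
    )
    dist_tae <- pmax(dist_tae, 0)

    # zone bin index for gradient modulation (1..3 by depth interval)
    bin_idx <- rep(NA_integer_, n_cells)
    ct_depth <- pos$y - tae_bottom
    for (i in seq_len(nrow(zones))) {
      sel <- pos$zone %in% zones$zone[i]
      bin_idx[sel] <- i
    }

    features <- if (config$modality == "transcript_count") {
      .sample_counts(config, cell_type, bin_idx)
    } else {
      .sample_intensities(config, cell_type)
    }

    ids <- sprintf("c%06d", seq_len(n_cells))
    cells <- cell_table(data.frame(
      cell_id = ids,
      section_id = config$section_id,
      subject_id = config$subject_id,
      condition = config$condition,
      x = pos$x, y = pos$y,
      unit = "um",
      cell_type = cell_type,
      stringsAsFactors = FALSE
    ))
    rownames(features) <- ids
    truth <- data.frame(
      cell_id = ids,
      section_id = config$section_id,
      zone = pos$zone,
      cell_type = cell_type,
      dist_tae = dist_tae,
      stringsAsFactors = FALSE
    )
    attr(truth, "gradients") <- config$gradients
    attr(truth, "lr_pairs") <- data.frame(
      ligand = c("CSF3", "SAA1"),
      receptor = c("CSF3R", "FPR1"),
      niche = c("TAE", "NeutCT"),
      stringsAsFactors = FALSE
    )
    list(cells = cells, features = features, truth = truth)
  })
}

.sample_counts <- function(config, cell_type, bin_idx) {
  em <- config$expression
  mu <- em$mu
  n <- length(cell_type)
  grads <- config$gradients
  out <- matrix(0, n, nrow(mu), dimnames = list(NULL, rownames(mu)))
  stromal <- cell_type %in% c("Fibroblast", "Endothelial")
  for (g in seq_len(nrow(mu))) {
    gene <- rownames(mu)[g]
    m <- mu[g, cell_type]
    gi <- match(gene, grads$gene)
    if (!is.na(gi)) {
      mult <- rep(1, n)
      has_bin <- stromal & !is.na(bin_idx)
      mm <- c(grads$m1[gi], grads$m2[gi], grads$m3[gi])
      mult[has_bin] <- mm[bin_idx[has_bin]]
      if (config$condition == "P" && grads$program[gi] == "proximal") {
        mult[stromal] <- mult[stromal] * config$f_prox
      }
      m <- m * mult
    }
    out[, g] <- stats::rnbinom(n, size = em$theta, mu = m)
  }
  feature_matrix(out, "transcript_count")
}

.sample_intensities <- function(config, cell_type) {
  im <- config$expression
  n <- length(cell_type)
  out <- matrix(0, n, nrow(im$meanlog), dimnames = list(NULL, rownames(im$meanlog)))
  for (g in seq_len(nrow(im$meanlog))) {
    out[, g] <- stats::rlnorm(n, meanlog = im$meanlog[g, cell_type], sdlog = im$sdlog)
  }
  feature_matrix(out, "protein_intensity")
}

#' Generate a cohort of synthetic sections
#'
#' One section per synthetic subject. Per-subject seeds are derived
#' deterministically from the base seed, and a subject-level random effect
#' (density jitter uniform in +/-20%) is applied so that group comparisons
#' see realistic between-subject variance.
#'
#' @param n_H,n_P Number of healthy and diseased subjects.
#' @param base_config A [tissue_config()] used as the template (its
#'   condition and identifiers are overridden per subject).
#' @param seed Base integer seed.
#' @return A list of [generate_section()] results, one per subject.
#' @export
generate_cohort <- function(n_H, n_P, base_config = tissue_config(), seed = 1L) {
  stopifnot(n_H >= 0, n_P >= 0)
  conditions <- c(rep("H", n_H), rep("P", n_P))
  subj_num <- c(seq_len(n_H), seq_len(n_P))
  out <- vector("list", length(conditions))
  for (i in seq_along(conditions)) {
    cond <- conditions[i]
    subject <- sprintf("%s%02d", cond, subj_num[i])
    subj_seed <- (as.integer(seed) + 7919L * i) %% .Machine$integer.max
    cfg <- base_config
    cfg$condition <- cond
    zd <- .default_zones(cond)
    scale_ <- cfg$zone_scale %||% 1
    zd$zones$dist_lo <- zd$zones$dist_lo * scale_
    zd$zones$dist_hi <- zd$zones$dist_hi * scale_
    cfg$zones <- zd$zones
    cfg$composition <- zd$composition
    cfg$subject_id <- subject
    cfg$section_id <- paste0(subject, "_s1")
    cfg$seed <- subj_seed
    jitter <- zm_with_seed(subj_seed + 1L, stats::runif(1, 0.8, 1.2))
    out[[i]] <- generate_section(cfg, density_scale = jitter)
  }
  out
}

#' Bind a cohort of sections into one cell table, feature matrix, and truth
#'
#' @param sections A list as returned by [generate_cohort()].
#' @return A list with combined `cells`, `features`, `truth`.
#' @export
combine_sections <- function(sections) {
  cells <- do.call(rbind, lapply(sections, function(s) as.data.frame(s$cells)))
  feats <- do.call(rbind, lapply(sections, function(s) unclass(s$features)))
  truth <- do.call(rbind, lapply(sections, function(s) s$truth))
  rownames(cells) <- NULL
  rownames(feats) <- paste(cells$section_id, cells$cell_id, sep = ":")
  mod <- modality(sections[[1]]$features)
  attr(truth, "gradients") <- attr(sections[[1]]$truth, "gradients")
  attr(truth, "lr_pairs") <- attr(sections[[1]]$truth, "lr_pairs")
  list(
    cells = cell_table(cells),
    features = feature_matrix(feats, mod),
    truth = truth
  )
}
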