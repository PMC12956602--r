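# Default pipeline configuration. Values mirror the package defaults:
# neighbourhood size 30 for protein-imaging tables (50 for spatial
# transcriptomics), >= 200 reference-niche cells per section, a 3000-unit
# distance threshold, and 0-100 / 100-500 / 500-1500 um stromal bins.
cohort:
  n_H: 8
  n_P: 10
section:
  width_um: 1000
  density_per_mm2: 3000
niche:
  k_neighbors: 30
  n_clusters: 6
  weighting: inverse_distance
zonation:
  ref_niche: TAE
  min_cells: 200
  max_distance: 3000
  bins: [0, 100, 500, 1500]
  immune_niches: [NeutCT, T-B-APC, plasma]
  stromal_types: [Fibroblast, Endothelial]
  genes: [SELE, ICAM1, CXCL1, SAA1, CCL19, HLA-DMB, CXCL12, COL16A1,
          ACTB, GAPDH, B2M, RPL13A, EEF1A1, TUBB]
phenotype:
  rules: null
lr:
  pairs: null
  fraction_cutoff: 0.1
transfer:
  n_ref: 2000
  n_query: 2000
  n_types: 5
  batch_shift: 1.0
  noise_sd: 0.1
  n_pcs: 30
  n_align_iters: 10
  k: 15
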