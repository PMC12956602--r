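# zonemap

Spatial immune zonation analysis for segmented cell maps of barrier
tissue.

At exposed mucosal barriers such as the human gingiva, immune cells are
not scattered uniformly: a thin, permeable tooth-associated epithelium
(TAE) is underlined by a neutrophil-rich connective-tissue band
(0–100 µm), a T/B/antigen-presenting-cell aggregate zone (100–500 µm),
and — in periodontitis — a deep plasma-cell zone (500–1,500 µm), while the
stromal compartment expresses distance-graded gene programs that support
this layering. `zonemap` packages the analysis chain for quantifying this
organisation from segmented per-cell tables (multiplexed protein imaging
or imaging-based spatial transcriptomics):

* **spatial I/O** — CSV/TSV cell tables, MatrixMarket count matrices,
  boundary-inclusive region-of-interest cropping, pixel→µm conversion;
* **phenotyping** — per-marker Gaussian-mixture auto-gating on
  log1p intensities with rescaling to [0, 1] (gate ↦ 0.5), hierarchical
  rule-based phenotype assignment, per-phenotype k-means subclustering;
* **niche detection** — k-nearest-neighbour neighbourhood matrices
  (self excluded, per section; k = 30 for protein imaging, 50 for spatial
  transcriptomics), k-means niche clustering, manual merge maps,
  composition (log10 counts + 1) and condition-proportion tables;
* **zonation** — sections filtered to ≥ 200 reference-niche cells, exact
  per-cell minimum distance to the reference epithelium, per-niche counts
  and mean distances under an inclusive 3,000-unit threshold, and the
  distance-binned stromal comparison: per-subject proportions of stromal
  cells expressing each gene in [0,100), [100,500), [500,1500) µm bins,
  compared H vs P by a two-sided Mann–Whitney U test (exact for combined
  n ≤ 20) with significant / trend / ns classes;
* **statistics** — rank-sum differential expression with
  Benjamini–Hochberg correction, normalised-and-scaled dot-plot means,
  gene-signature scoring;
* **ligand–receptor coexpression** — fraction-based min-rule scoring of
  pair coexpression within niches with predominant-cell-type attribution;
* **label transfer** — batch-aligned joint PCA embedding and k-NN voting
  from a dissociated single-cell reference onto spatial cells, with
  concordance and niche-enrichment summaries;
* **synthetic tissue** — a layered-mucosa generator that plants the zones,
  gradients, condition effects and ligand–receptor pairs above with full
  ground truth, used to validate every stage.

The central statistic of the zonation module is, for immune niche $N$ and
reference niche $R$ in a section, the mean over cells $i \in N$ of the
nearest-reference distance

$$d_i = \min_{j \in R} \lVert (x_i, y_i) - (x_j, y_j) \rVert_2,$$

restricted to $d_i \le 3{,}000$ units, alongside the count of such cells.
Stromal profiles use the subject-level proportion
$p_{s,b,g} = \#\{i \in \text{stroma}, d_i \in b, c_{ig} > 0\} /
\#\{i \in \text{stroma}, d_i \in b\}$ per distance bin $b$ and gene $g$.

## Worked example

```r
library(zonemap)

# a diseased synthetic section with planted architecture
sec <- generate_section(tissue_config(condition = "P", seed = 7))
sec$cells$niche <- sec$truth$zone          # or cluster_niches() on real data

filter_sections(sec$cells, "TAE", min_cells = 200)
#> [1] "P_s1"

niche_distance_summary(sec$cells, "TAE",
  c("NeutCT", "T-B-APC", "plasma"), max_distance = 3000)
#>   section_id   niche n_within mean_distance
#> 1       P_s1  NeutCT      928         55.84
#> 2       P_s1 T-B-APC     1184        310.70
#> 3       P_s1  plasma     1225       1005.07
```

The mean distances reproduce the qualitative zonation: the neutrophil band
sits ~56 µm from the TAE, the lymphoid aggregate ~310 µm, and the plasma
zone deepest at ~1,005 µm. The stromal gradient is visible in the binned
expressing proportions:

```r
prof <- bin_stromal_expression(sec$cells, sec$features,
  stromal_types = c("Fibroblast", "Endothelial"),
  genes = c("SELE", "CXCL1", "CXCL12"))
head(as.data.frame(prof))
#>   subject_id condition       bin   gene n_stromal proportion
#> 1          P         P   [0,100)   SELE       321 0.54828660
#> 2          P         P   [0,100)  CXCL1       321 0.52336449
#> 3          P         P   [0,100) CXCL12       321 0.03738318
#> 4          P         P [100,500)   SELE       326 0.19631902
#> 5          P         P [100,500)  CXCL1       326 0.25153374
#> 6          P         P [100,500) CXCL12       326 0.14110429
```

Over 54% of stromal cells within 100 µm of the TAE express the planted
proximal genes (SELE, CXCL1) versus ~20–25% at 100–500 µm, while the
distal chemokine CXCL12 runs the other way. On a cohort,
`compare_groups(prof)` tests the health-vs-disease difference of these
proportions per bin and gene. The full chain (simulate → niche → zonate →
DE → ligand–receptor) runs as one deterministic demo:

```r
run_pipeline("demo", outdir = "zonemap_out", seed = 42)
```

or from a shell via the thin wrapper `inst/cli/zonemap.R`.

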