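---
title: "Methods: spatial immune zonation analysis with zonemap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial immune zonation analysis with zonemap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`zonemap` analyses immune zonation in segmented spatial maps of barrier
tissue — the motivating system is the human gingiva, where a thin,
permeable tooth-associated epithelium (TAE) is underlined by a layered
immune compartment: a neutrophil-rich connective-tissue band immediately
beneath the barrier, a T/B/antigen-presenting-cell (T-B-APC) aggregate at
intermediate depth, and, in periodontitis, a deep plasma-cell zone. The
package takes per-cell tables from segmented spatial assays (multiplexed
protein imaging or imaging-based spatial transcriptomics) and provides the
full chain: phenotyping, niche detection, barrier-proximity statistics,
distance-binned stromal expression comparison, ligand–receptor
coexpression, and cross-modality label transfer. A synthetic
layered-mucosa generator plants all of these structures with known ground
truth, so every stage is validated end to end.

## The cell table and its conventions

All stages operate on a `cell_table`: one row per segmented cell with
centroid coordinates, section/subject/condition metadata, and
progressively attached `cell_type` and `niche` labels. Coordinates are
Cartesian with y increasing downward (the image convention); since every
statistic downstream consumes only distances, the y-direction choice is
inert and matters only for plotting. Tables in pixel units carry a
`pixel_size_um` column (0.444 um/px is the typical confocal value for this
kind of data) and `to_um()` converts them; the conversion is idempotent.
Region-of-interest cropping (`crop_roi()`) is **boundary inclusive**: a
centroid exactly on the polygon edge is retained. Inclusion is the
deterministic reading of "within the region" and is pinned by tests
against an independent point-in-polygon oracle.

A companion `feature_matrix` holds cells x features non-negative values,
either `transcript_count` (integers) or `protein_intensity`. "Expressing"
means count > 0 for transcripts — the minimal-assumption definition for
imaging-based transcriptomics with shallow per-cell counts — and gated
value > 0.5 for proteins.

## Marker gating and phenotyping

`fit_gates()` fits, per marker, a two-component Gaussian mixture to
`log1p(intensity)` by EM (via mclust, equal/unequal-variance models chosen
by BIC; deterministic under the supplied seed). log1p rather than log
tolerates zero intensities. The gate defaults to the intersection point of
the two weighted component densities between the means; the posterior
responsibility = 0.5 crossing is available as `method = "responsibility"`
(the two coincide as separation grows; the density intersection is the
default because it is also well defined when one component dominates). A
monotone piecewise-linear map then rescales each marker to [0, 1] with the
gate at 0.5, so "positive" is always "gated value > 0.5".

One practical consequence of log1p: multiplying all intensities by a
constant shifts the fitted gate by the log of that constant only up to a
`log(1 + 1/x)` curvature term, so scale equivariance is exact only for
bright markers. The test suite checks the property at 1e-3 tolerance on
high-magnitude intensities.

Phenotypes are assigned by walking a user-declared rule hierarchy
(`assign_phenotypes()`): a rule matches when all its `pos` markers exceed
0.5, at least one `anypos` marker exceeds 0.5, and all `neg` markers are
at or below 0.5; cells descend to the deepest matching rule and ties among
sibling rules break on the larger mean of positive-marker gated values —
deterministic and monotone in the evidence. Unmatched cells are labelled
`"unknown"` and are conventionally excluded downstream. `subcluster()`
refines one phenotype at a time by k-means (10 restarts, fixed seed) on a
marker subset, naming subclusters by descending size.

## Niche detection

`build_neighborhood_matrix()` summarises each cell's microenvironment as
the weighted mean of its k nearest neighbours' feature rows (one-hot cell
types by default, so rows are neighbourhood composition vectors summing
to 1). Three conventions matter:

* **Self is excluded** from the neighbourhood, which makes the k = 1 case
  a pure neighbour readout.
* Neighbour search never crosses section boundaries — sections are
  physically distinct tissues; sections with <= k cells are skipped with a
  warning.
* Weights are inverse-distance, `w ∝ 1/(d + 1 um)`, with uniform weights
  available by flag; ties at the k-th distance break on cell id so results
  are independent of row order.

Defaults follow the two modalities: k = 30 for protein imaging, k = 50 for
spatial transcriptomics. `cluster_niches()` runs k-means (10 restarts,
fixed seed) on the neighbourhood rows and renames clusters by descending
size, so identical partitions get identical names across seeds;
`niche_sweep()` reports inertia over a (k, cluster-count) grid, and
`merge_niches()` applies a manual raw-cluster to named-niche map, which is
how compositionally equivalent clusters are merged after inspection.

## Barrier-proximity zonation

`distance_to_reference()` computes each cell's exact minimum Euclidean
distance to any reference-niche (e.g. TAE) cell within its section.
`filter_sections()` first restricts to sections with at least 200
reference cells — a small reference band gives unstable distances.
`niche_distance_summary()` then reports, per section and immune niche, the
number of cells within a maximum distance (3,000 units, inclusive; a guard
against section-size variation) and the mean of those distances. The mean
is taken over per-cell minimum distances, which reads as zonal depth and
is stable to the length of the reference band; the all-pairs average is
available via `method = "allpairs"`.

`bin_stromal_expression()` profiles the stromal compartment as a function
of barrier distance using half-open bins, by default [0, 100), [100, 500)
and [500, 1500) um (cells at 1,500 um or beyond are excluded). Sections
are pooled within subject, and the per-subject proportion of stromal cells
expressing each gene is the unit of analysis — group comparisons are
therefore subject-level, not cell-level. `compare_groups()` applies a
two-sided Mann–Whitney U test per (bin, gene): exact when the combined n
is at most 20 (full enumeration of group assignments when ties are
present), normal approximation with tie and continuity corrections
otherwise. Results are classed `significant` (p <= 0.05), `trend`
(0.05 < p <= 0.1; the closed upper bound keeps the canonical 3v3 extreme
case, exact p = 0.1, in the trend class), or `ns`. No multiplicity
correction is applied here — the classes mirror how such panels are
reported — while `bh_adjust()` is available and is applied in the DE
module.

## Statistical kernels

Counts are normalised to 10,000 per cell and log1p-transformed (a
declared, reproducible default; intensities skip the library-size step).
`wilcoxon_de()` runs the shared rank-sum kernel per gene at cell level
(P versus H), with log2 fold changes from normalised group means
(pseudocount 1e-9) and Benjamini–Hochberg correction; a subject-level
pseudobulk flag exists because pooled cell-level testing treats cells as
independent. `dotplot_stats()` z-scores group means per gene across groups
with the population SD (dot plots compare a handful of groups), mapping
zero-variance genes to 0 rather than NaN. `signature_score()` averages
per-gene z-scores over a gene set (e.g. a high-endothelial-venule
signature) and drops missing genes with a warning.

## Ligand–receptor coexpression

`niche_lr_scores()` calls a pair coexpressed in a niche when both genes
are expressed in at least a fraction cutoff (default 0.1) of the niche's
cells, scoring the pair by the smaller of the two fractions. Fractions are
robust to library-size differences, the statistic is monotone in the
cutoff, and no permutation null is attached — the output is a descriptive
coexpression map, not a significance claim. Each gene's predominant
expressing cell type within a niche is the type with the highest mean
normalised expression among types with at least 10 cells there, which
guards against single-cell artifacts.

## Label transfer

`fit_joint_embedding()` concatenates reference and query on shared genes
(at least 50 by default), z-scales per gene over the union, and takes a
PCA (30 components, signs canonicalised so the largest-magnitude loading
is positive — this makes the embedding reproducible under gene and cell
permutations). Batch alignment is a soft-cluster centroid-matching scheme:
soft k-means responsibilities in PC space, per-batch per-cluster soft
centroids compared to the global centroid, and each cell shifted by its
responsibility-weighted batch offsets, iterated (10 rounds by default;
0 gives plain joint PCA). This is a deliberately simple, fully testable
alignment — it removes planted constant batch shifts by orders of
magnitude and is validated on ground-truth transfers; a hook for an
external harmonisation method is the model's `ref_embedding`/
`query_embedding` slots, which downstream functions consume unchanged.
`transfer_labels()` votes among the k = 15 nearest reference cells
(ties to the label with the smaller mean neighbour distance) and reports
the vote fraction as confidence; `concordance_and_enrichment()`
row-normalises the transferred-versus-spatial cross-tabulation and the
niche distribution of each transferred label.

## The synthetic tissue generator

`generate_section()` builds a virtual section as horizontal bands: an oral
epithelium (OE) band and a TAE band (100 um each), then connective-tissue
zones defined by distance from the TAE's lower edge — NeutCT at
[0, 100) um, T-B-APC at [100, 500) um, and at [500, 1500) um either a
plasma zone (disease) or cell-poor fibrous tissue (health). Cells are
placed by a homogeneous Poisson process per band and typed by per-zone
composition vectors (e.g. the NeutCT zone is 60% neutrophils; the TAE band
is 80% odontogenic epithelium and 20% infiltrating neutrophils). Counts
are negative binomial (dispersion theta = 2) with per-type marker means;
intensities are log-normal. These are the field-standard noise families
for the two modalities.

Chosen realism defaults, stated once: baseline connective-tissue
cellularity 3,000 cells/mm^2; epithelium twice as dense (stratified
epithelium is considerably more cellular than stroma); the deep zone at
0.4x baseline (deep fibrous connective tissue is collagen-rich and
cell-poor). Planted stromal gradients follow the three bins with
multipliers 1/0.25/0.08 for the proximal program (SELE, ICAM1, CXCL1,
SAA1), 0.2/1/0.3 for the intermediate program (CCL19, HLA-DMB) and
0.1/0.3/1 for the distal program (CXCL12, COL16A1); six flat housekeeping
genes act as negative controls. Disease effects: neutrophil-band density
x3, proximal stromal gene means x2, and the plasma zone enabled only in
disease. A planted ligand–receptor pair (CSF3 in TAE epithelium, CSF3R in
neutrophils) is recoverable in the TAE niche and nowhere else.
`generate_cohort()` derives per-subject seeds deterministically and
applies +/-20% subject-level density jitter so group tests see realistic
between-subject variance.

What the generator does **not** emulate: curved tissue geometry (zones are
straight bands — only the distance-to-TAE structure, which is all the
analysis consumes, is preserved), segmentation errors, spatial
autocorrelation of expression within a type beyond the planted gradients,
cell-shape features, and batch effects between sections. Passing tests
therefore demonstrate correctness of the algorithms on planted structure,
not robustness to every artifact of real imaging data.

## Numerical and design notes

* Nearest-neighbour and nearest-reference searches are exact brute-force
  computations, chunked to bound memory; tests pin them to O(n^2) oracles
  at 1e-9.
* All stochastic routines take explicit seeds and run under a
  state-preserving RNG scope; the pipeline derives per-stage seeds from
  one root seed, and the demo is byte-identical across runs at a fixed
  seed.
* k-means everywhere uses 10 restarts and a fixed seed; cluster naming by
  descending size makes labels stable across seeds when partitions agree.
* Degenerate inputs have defined behaviour: constant markers are a gating
  error; fully tied rank-sum data give p = 1; zero-variance genes scale to
  0 in dot plots; sections without reference cells are skipped with a
  warning, not an error.
* Problem sizes used by the validation suite (our choices for a laptop-
  scale run): ~8,000-cell sections for niche recovery (adjusted Rand index
  versus planted zones ~0.93), cohorts of 8 healthy and 10 diseased
  subjects for the distance-bin comparisons, 2,000 null simulations for
  rank-test calibration, and 2,000-cell reference/query splits for label
  transfer.

## Known limitations

The batch alignment is a simple centroid-matching analog, not a
reimplementation of published harmonisation methods; heavily non-linear
batch effects would need an external corrector. Cell-level DE treats
cells as independent (the pseudobulk flag is the conservative
alternative). The ligand–receptor score is descriptive. The Mann–Whitney
exact-enumeration path is quadratic-combinatorial and only used for
combined n at most 20.
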