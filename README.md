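# spatialcoloc

Spatial colocalization and neighborhood analysis for high-resolution
spatial transcriptomics.

Segmented in-situ platforms (e.g. 10x Xenium) yield a table of cell
centroids with cell-type labels and, optionally, a cell × gene count
matrix. A recurring question in inflamed tissue — synovium, tumors,
autoimmune lesions — is *which cell types organize together in space*:
which pairs sit within interaction distance more often than chance,
where exactly two types co-occur at cell–cell contact range, what
microenvironmental niches the tissue decomposes into, how expression
programs vary with distance to a landmark cell type, and whether T and
B/plasma cells form tertiary lymphoid structures (TLS). `spatialcoloc`
implements that toolkit, together with seeded synthetic-tissue
generators so every component is validated without access to patient
data.

## Methods at a glance

* **Neighborhood enrichment** (`enrichment_test`). For each directed
  type pair (A→B) the statistic is the mean, over A-cells with at least
  one neighbor within radius *r* (default 30 µm), of the fraction of B
  among the neighbors. The null shuffles cell-type labels within each
  sample with coordinates fixed; with observed statistic *s* and null
  draws *s\*₁…s\*ₙ*,

  z = (s − mean s\*) / sd s\*,  p = (1 + #{s\* ≥ s}) / (n + 1),

  with Benjamini–Hochberg adjustment across all tested directed pairs.
  An exhaustive enumeration oracle (`exhaustive_null`) gives exact p on
  small instances.
* **Single-spot colocalization** (`coloc_score`). Per-cell score
  f_A(i)·f_B(i), where f_T(i) = Σ_j w(d_ij) over type-T cells within
  radius (default 10 µm), w linear (1 − d/r), uniform or Gaussian.
  Zero unless both types contribute mass; `coloc_significance` adds a
  per-cell permutation p, and `correlate_signal_with_coloc` ranks
  externally inferred ligand–receptor signals by Spearman correlation
  with the field.
* **Niches** (`niche_composition`, `cluster_niches`,
  `annotate_niche_classes`). Each cell is summarized by the cell-type
  composition of its 30 nearest within-sample neighbors; k-means
  (k-means++ seeding, default 30 niches) groups cells into niches,
  which are annotated into lineage-level classes by z-scoring lineage
  shares across niches.
* **Distance–expression profiles** (`nearest_distance_to_type`,
  `binned_distance_profile`, `module_score`). Distance to the nearest
  cell of a target type, per-bin expression means for display, and
  Spearman statistics computed on the *unbinned* per-cell pairs;
  control-matched gene-module scores (mean of set genes minus matched
  controls drawn from expression bins).
* **TLS detection** (`detect_tls`, `tls_distance_composition`,
  `tls_proximity_summary`). Cells with high T–B/plasma colocalization
  scores (per-sample quantile over nonzero scores) are linked by single
  linkage (30 µm); components of ≥ 20 cells become regions with convex
  hulls, then characterized by cell-type composition versus distance to
  the nearest TLS B cell, 10 µm proximity shares, and per-µm decay
  slopes with 95% CI from OLS.
* **Synthetic tissues** (`sim_concentric`, `sim_layers`, `sim_csr`,
  `sim_coloc_aggregate`, `sim_tls_tissue`, `sim_gradient_tissue`,
  `sweep_enrichment`). Seed-deterministic generators with
  machine-readable ground truth: planted proximity gaps (hard minimal
  inter-type distances), mixed aggregates, TLS-like cores with immune
  shells, and expression gradients calibrated to a target Spearman rho
  via a Gaussian copula.

## Worked example

```r
library(spatialcoloc)

# a ring of type A, a ring of type B 20 um away, a decoy ring C 150 um
# away, and 4000 background cells
sim <- sim_concentric(n_per_type = 500, gap_um = 20, seed = 7,
                      decoy_gap_um = 150)
res <- enrichment_test(sim$cells, enrichment_config(n_perm = 1000, seed = 7))
res
#> enrichment_result: 4 types, 16 directed pairs, montecarlo null (1000 draws)
#>   pairs with p_adj < 0.05: 6
subset(res$table, anchor_type == "A")[, c(1:4, 6:8)]
#>   anchor_type target_type observed_stat perm_mean     z   p_perm   p_adj
#>             A           A         0.592    0.0905  63.0 0.000999 0.00266
#>             A           B         0.304    0.0912  36.6 0.000999 0.00266
#>             A          BG         0.103    0.7275 -62.5 1.000000 1.00000
#>             A           C         0.000    0.0909 -15.8 1.000000 1.00000
```

Around A-cells, 30% of neighbors are B although B is only 9% of the
tissue (z = 36.6, p_adj = 0.0027): the planted 20 µm adjacency is
detected. The decoy ring C, 150 µm away, is correctly not enriched.

```r
tls <- sim_tls_tissue(seed = 7)  # 2 B-cell cores + T cells + shells
fld <- coloc_score(tls$cells, "T", "B/plasma", coloc_config(radius_um = 10))
regions <- detect_tls(fld, tls$cells,
                      tls_config(score_quantile = 0.1,
                                 linkage_radius_um = 30, min_cells = 20))
regions
#> tls_regions: 2 region(s) [T vs B/plasma]
#>   region 1 (sample sim1): 151 cells, mean score 3.692
#>   region 2 (sample sim1): 146 cells, mean score 4.522
comp <- tls_distance_composition(tls$cells, regions, "B/plasma",
                                 bins = seq(0, 30, 3))
tls_proximity_summary(comp, near_radius = 10)
#>   cell_type   n pct_within_near slope_per_um ...
#>    B/plasma 160           100.0           NA
#>           T 160            98.1    -0.042917
#>     Tph/Tfh  80            28.7     0.000238
#>     Stromal  28            57.1    -0.004960
```

Both planted aggregates are recovered; T cells are packed against TLS B
cells (98% within 10 µm, decaying ~0.04 in proportion per µm), while
the stromal background shows no decay (CI covers 0).

## Command line

A single entry point exposes the pipeline (launcher in `inst/cli/`):

```sh
spatialcoloc simulate --pattern concentric --gap 20 --n 500 --seed 7 \
    --out cells.csv --truth-out truth.json
spatialcoloc enrich --cells cells.csv --radius 30 --n-perm 1000 --seed 7 \
    --min-cells 10 --out enrichment.tsv
spatialcoloc coloc --cells cells.csv --anchor T --target "B/plasma" \
    --radius 10 --kernel linear --out coloc.tsv
spatialcoloc tls --cells cells.csv --t-label T --b-label "B/plasma" \
    --quantile 0.9 --linkage 30 --min-cells 20 --out tls.tsv --geojson tls.geojson
```

Every run echoes its effective configuration as JSON next to its output;
identical configuration + seed reproduces outputs byte-for-byte at any
`--threads` value (permutation sub-seeds derive from the master seed by
counter).
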