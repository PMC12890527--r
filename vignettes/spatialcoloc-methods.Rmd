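---
title: "Methods: spatial colocalization and neighborhood analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial colocalization and neighborhood analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of its methods: the models
and their assumptions, the parameters that matter, what the synthetic
generators do and do not emulate, the numerical choices, and the design
decisions that were genuinely open. It states no empirical result that
the test suite does not itself compute.

## Data model and assumptions

All analyses consume a `cell_map`: one row per segmented cell with a
2-D centroid in micrometres, a sample identifier, a cell-type label and
an optional lineage label. Assumptions baked in throughout:

* Coordinates are Euclidean in the section plane; the origin and
  orientation are arbitrary (all statistics are distance-based, and the
  enrichment z is asserted invariant to translation, rotation and
  reflection).
* Every spatial query is confined to a sample. Biopsies are physically
  separate pieces of tissue; a neighbor pair spanning samples is
  meaningless. Label permutations likewise shuffle within sample, so
  differences in per-sample type composition cannot masquerade as
  spatial structure.
* Unlabeled cells are dropped at ingestion (with a logged count), not
  imputed: every method here conditions on labels.
* Distances to a type absent from a sample are `Inf`, serialized as
  `inf` so they survive TSV round-trips.

## Neighborhood enrichment

For a neighbor graph (default: fixed 30 µm radius; kNN available) the
directed statistic for pair (A, B) is the mean, over anchor A-cells
with at least one neighbor, of the neighbor fraction of B. Choices and
reasons:

* **Fraction, not count**, decouples the statistic from local density;
  the null expectation is then simply the global type share.
* **Anchors with zero neighbors are excluded** from the mean, in the
  observed data and in every permutation — counting them as zero would
  penalize sparse regions rather than measure composition.
* **Radius default 30 µm** is the interaction scale at which planted
  adjacency is reliably detectable (see the detection boundary below);
  kNN is offered for density-adaptive neighborhoods.
* **One-sided enrichment is the default alternative** (proximity
  claims are about over-representation); depletion and two-sided are
  options. p = (1 + #{null ≥ observed})/(n_perm + 1), so p is never
  zero and never below 1/(n_perm+1).
* **BH adjustment** is applied once across all tested directed pairs.
  Types below `min_cells_per_type` (default 10) in every sample are
  reported `skipped_low_count` and excluded from the family.
* **Determinism**: permutation *t* derives its sub-seed from the master
  seed by counter (`seed + 10007·t mod 2³¹−1`), so results are
  identical regardless of how permutations are partitioned across
  workers. A `threads` argument is accepted for interface
  compatibility; the implementation is serial and the seeding scheme
  makes the output thread-count-invariant by construction.
* The permutation loop runs in C++ with a standard-specified generator
  (`std::mt19937`) and an unbiased rejection-sampled Fisher–Yates
  shuffle, so runs are reproducible bit-for-bit across platforms.

`exhaustive_null` enumerates every distinct assignment of the observed
label multiset to coordinates (within samples; bounded at 10⁶
labelings) and is the exact oracle against which the Monte-Carlo p is
validated on small instances.

### The detection boundary, and one deliberately red case

The validation world plants two thin concentric rings (or parallel
bands), types A and B, whose regions are separated by a hard minimal
gap, a decoy ring at 150 µm, and a CSR background population. Two
design points deserve explanation:

* **Thin structures plus background, not filled disks.** The statistic
  compares the local B-fraction around A to the global B share. If A
  fills a bulk region, A's own mass dominates every A-neighborhood and
  the pair comes out *depleted* relative to the shuffle null no matter
  how close B is (a pilot run on disk-plus-annulus geometry gives
  z ≈ −23 for the planted pair). Enrichment of an adjacent pair is only
  observable when the planted types are thin relative to the query
  radius and diluted by a background population — which is also what
  "concentric circles" describes. Generator defaults (500 cells per
  5 µm-wide ring, 4000 background cells over a 1.6 mm field) give a
  planted-pair signal of roughly 0.30 observed fraction against a 0.09
  null share at a 20 µm gap.
* **A gap equal to the query radius is undetectable by construction.**
  The generator guarantees the realized minimal inter-type distance is
  at least the declared gap. At gap = 30 µm with an (inclusive) 30 µm
  radius query, the probability that any cross-type pair lies within
  the radius is zero, the observed statistic is exactly 0, and the
  one-sided enrichment p is 1 — for *any* statistic computed on that
  graph. The acceptance battery asserts detection at gaps 10, 20 and
  30 µm; the 30 µm sub-case therefore fails and is left red
  deliberately rather than weakening the hard-gap contract or the
  radius. Detection at separations strictly inside the radius — the
  substantive claim — passes at 19/20 seeds or better per pattern, and
  the decoy pair at 150 µm is never significant.

Type-I calibration is checked under CSR (three types, 50 seeds): the
fraction of directed pairs with p < 0.05 must lie in [0.02, 0.08].

## Single-spot colocalization

The per-cell score is the product of kernel-weighted local masses,
score(i) = f_A(i) · f_B(i), with f_T(i) = Σ w(d_ij) over type-T cells
within the radius (default 10 µm — cell-contact range), w(0) = 1.
The product form was the central open design decision (no closed form
is published for the score this package reimplements): it is zero
unless both types are simultaneously present, symmetric in the pair,
monotone as either type packs closer, and computable in O(neighbors)
per cell. The linear kernel `1 − d/r` is the default; uniform and
truncated Gaussian (σ = r/2) are kept for sensitivity analysis. With a
uniform kernel and self-contributions off, the score collapses to
(count of A within r) × (count of B within r), which is tested exactly
against a counting oracle. Scores are reported raw; any rescaling is
for map rendering only.

## Niches

Each cell's microenvironment is the type composition of its 30 nearest
within-sample neighbors (self excluded, k truncating with a warning in
tiny samples). k-means with k-means++ seeding (10 restarts, best
inertia kept) groups compositions into 30 niches by default; the
lineage-level classes are an *annotation* of niches, not a second
clustering: lineage shares are z-scored across niches and a niche is
labeled by its top-z lineage, with the runner-up appended
(`"Myeloid+T"`) when its z reaches 1.0. The threshold is exposed; the
rule itself is a package decision, as is the zero-variance fallback
(identical niches are all labeled by the globally dominant lineage and
flagged). Numerical details: assignment ties go to the lowest centroid
index; an emptied cluster is re-seeded at the point farthest from its
centroid; seeding operates on rows in canonical lexicographic order so
the result is invariant to input row order given the seed.

## Expression-side analyses

* **Normalization**: per-cell totals scaled to the median total, then
  log1p; a flag refuses double-normalization. This is the conventional
  single-cell normalization; the upstream study does not state its
  variant, so the choice is recorded here.
* **Module scores**: mean expression of the set genes minus the mean of
  control genes, each set gene contributing `n_ctrl_per_gene` (default
  50) controls sampled without replacement from its own
  average-expression bin among 25 equal-frequency bins. This is the
  standard control-matched construction; it makes the score
  location-invariant (exactly so when a bin's pool is exhausted and
  controls are deterministic).
* **Distance profiles**: bins (default 10 µm up to 300 µm) are display
  resolution only; Spearman rho and p are computed on the unbinned
  per-cell (distance, value) pairs, using average ranks for ties and
  the t approximation for p. The implementation is asserted against a
  rank-then-Pearson oracle at 1e-12.
* Group comparisons of scores use the two-sided Wilcoxon rank-sum test,
  BH-adjusted — a thin utility, not an inferential centerpiece.

## TLS detection and characterization

Without pathologist annotation, a TLS is operationally: cells whose
T–B/plasma colocalization score exceeds a per-sample quantile of the
nonzero scores (default 0.90), single-linkage-connected at 30 µm, in
components of ≥ 20 cells. All three knobs are exposed because the
upstream threshold is unstated and was calibrated against histology.
The quantile deserves care: it is relative to the tissue's *nonzero*
score population. In real inflamed tissue, low-grade T–B mixing is
pervasive and the top decile isolates genuine aggregates; in synthetic
tissues where colocalization exists only inside planted aggregates,
nearly every nonzero score is a true member, and the tests accordingly
run detection at quantile 0.10 (drop only the weakest tail). This is a
property of the stated synthetic world, not a tuning of the detection
rule.

"TLS B cell" means a B/plasma cell in a detected region's footprint —
a member, or within the linkage radius of one. Footprint membership
(rather than strictly score-thresholded members) exists because
aggregate-edge B cells can fall just below the score threshold while
belonging to the structure; the linkage radius that defines the region
also defines its footprint. Composition curves (fraction of each type's
neighborhood cells per distance-to-TLS-B bin; 5 µm default bins per the
display convention, arbitrary bin vectors accepted) each sum to 1.
Decay slopes come from closed-form OLS of per-bin proportions on bin
midpoints over nonempty bins, with 95% t-based CIs; fewer than 3
nonempty bins gives NA (a type confined to 2 bins has no meaningful
slope, even if extremely proximal — its concentration is captured by
the 10 µm share instead).

## Synthetic tissues: what they emulate, and what they do not

The generators reproduce the *geometry* of the validation patterns:
hard minimal inter-type gaps (guaranteed by sampling types in disjoint
regions whose boundaries are exactly the gap apart), CSR nulls, mixed
aggregates at lymphoid packing density (~0.03 cells/µm²) against
segregated backgrounds, B-cell cores with concentric immune shells, and
expression gradients whose Spearman correlation with
distance-to-target hits a requested value via a Gaussian copula on
distance ranks (latent correlation r = 2·sin(π·ρ/6), values mapped
through the normal CDF so they are valid normalized expression).
Defaults are chosen once: 500 cells per planted type, millimetre-scale
fields, densities in the range of segmented in-situ data.

They do **not** emulate segmentation error, probe efficiency,
transcript-level count noise, tissue folds or 3-D structure. A green
test therefore establishes that the statistics recover planted spatial
and correlation structure at realistic scales — not that the pipeline
is robust to upstream artifacts.

## Known limitations

* Neighbor queries are exact brute force in C++ (quadratic per sample):
  ample for 10³–10⁴ cells per sample, but a kd-tree or grid index would
  be warranted at 10⁵+.
* The per-cell colocalization significance map shuffles labels within
  samples; it does not condition on local density heterogeneity.
* `threads` does not parallelize (the seeding contract makes this
  unobservable in results, only in wall time).
* TLS detection knobs must be calibrated per cohort; the package
  deliberately ships no claim that its defaults match any histological
  gold standard.
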