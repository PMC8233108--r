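---
title: "Methods: myelin-sensitive connectome weighting and its comparison machinery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: myelin-sensitive connectome weighting and its comparison machinery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(myeloconn)
```

## The problem

Structural connectomes model the cortex as a graph: nodes are parcellation
regions, edges are white-matter connections reconstructed by tractography.
The conventional edge weight is the number of streamlines (NOS) connecting
a region pair, a quantity driven by fibre geometry, seeding density and
tracking heuristics. A myelin-sensitive alternative weights the same edges
by a quantitative MRI scalar sampled along the connecting bundle — here the
longitudinal relaxation rate R1 = 1/T1 (units 1/s), which increases with
myelin content; white matter at 3T sits around 1.0–1.2 1/s. The two
weightings answer different questions ("how much wiring?" versus "how
myelinated is the wiring?"), and this package implements the machinery to
build both and to compare their network organization.

## Connectome construction

For one subject the inputs are a tractogram (3-D polylines in world mm), an
integer parcellation volume, and a scalar volume sharing the same space.
`build_connectome()` proceeds as follows.

* **Length filter.** Streamlines shorter than 20 mm or longer than 250 mm
  are discarded; the bounds are inclusive (a literal reading of the discard
  rule: strictly shorter/longer streamlines go). Both bounds are arguments.
* **Endpoint assignment.** Each terminal vertex maps to the label of its
  containing voxel; background endpoints fall back to the nearest labelled
  voxel centre within a configurable radius (default 2 mm, a common choice
  in connectome pipelines; radius 0 reduces to pure containment).
  Streamlines with an unassignable endpoint, or with both endpoints in the
  same region, carry no edge. The assignment rule is deliberately
  configurable because tracking toolchains differ on it.
* **Scalar sampling.** One sample per vertex, trilinear by default
  (nearest-voxel available). Vertices outside the volume contribute no
  sample.
* **Edge weights.** NOS is the bundle's streamline count; the scalar weight
  is the *median over the pooled samples of all the bundle's streamlines* —
  one median per bundle. The median is preferred over the mean because it
  is robust to outlier samples and assumes nothing about the distribution
  along the tract. The alternative convention (median of per-streamline
  medians) is available via `pooling = "per_streamline"` for sensitivity
  analysis. Even sample counts take the midpoint of the central order
  statistics. Pairs with fewer than `min_streamlines` streamlines
  (default 2; 5 as a conservative robustness setting) are zeroed in *both*
  matrices, and bundles with an empty sample list are dropped from both, so
  the NOS and scalar connectomes always share their support.

## Group consensus

Cohorts are pooled by the standard prevalence rule: an edge is kept when
present in at least `ceiling(prevalence * n_subjects)` subjects (default
50%). Kept edges take the median of their weights across the subjects *in
which they are present*; including absent subjects as zeros would drag the
consensus weight below every observed weight, which we consider
unrepresentative (`include_absent = TRUE` restores the literal
all-subjects median). The shared variance of two weightings is summarized
by an ordinary least-squares regression over the upper-triangle edges
present in both consensus networks (no log transform); R² is symmetric in
the two networks.

## Node metrics

NOS strength is the plain row sum `S_i = sum_j w_ij`. For the scalar
weighting a strength-style sum would conflate myelination with connection
count, so the package uses the streamline-count-weighted average
`S_i = sum_j w_ij v_ij / sum_j w_ij`, which is bounded by the incident
scalar values and invariant to a global rescaling of the counts. Isolated
nodes have no defined average and propagate as `NA`. Hubs are nodes at
least k sample standard deviations above the mean metric (k = 2, and 3 as
a conservative variant). With a constant metric the SD is zero and the hub
set is defined to be empty — declaring every node a hub in a degenerate
graph would be useless. Sample (n−1) SD is used throughout; the population
variant changes nothing qualitatively at cortical parcellation sizes.

## Modular structure

Partitions are scored by resolution-scaled modularity
`Q(gamma) = (1/2m) * sum_ij (A_ij - gamma * k_i k_j / 2m) delta(c_i, c_j)`
with the weighted configuration (Newman–Girvan) null `P_ij = k_i k_j / 2m`
and the conventional 1/2m normalization (which puts Q in the familiar
range; a single community at gamma = 1 scores exactly 0). Maximization is
a from-scratch two-phase Louvain implementation (greedy node moves, graph
aggregation) with the node visiting order shuffled by an explicit seed;
runs are bit-reproducible given `(matrix, gamma, seed)` and independent of
R's global RNG.

The resolution parameter is swept over 0.5–3 in steps of 0.1 (26 levels)
with many Louvain runs per level (1,000 at full scale). "Best" resolution
is a genuinely open choice: raw Q is monotonically decreasing in gamma for
a fixed partition, so maximizing Q across the grid degenerates to the
smallest gamma. The package therefore selects the gamma whose runs are
most mutually *stable*, measured by the mean pairwise z-scored Rand
coefficient (the pair-counting Rand statistic z-scored against the
hypergeometric fixed-module-size null); ties break toward the smaller
gamma, and the max-Q reading remains available behind
`selection = "max_q"`. Comparisons whose null variance vanishes (all runs
a single community) contribute stability 0, which correctly marks
degenerate resolutions as uninformative. With more than 150 runs per level
the pairwise statistic is computed over a seeded subsample of 10,000 run
pairs; half a million exact pairs per level would add cost and no
precision.

The representative partition at the selected resolution is a consensus
partition: the co-assignment (agreement) matrix of the runs is thresholded
at the chance level estimated from 100 independent label permutations of
each run, Louvain (gamma = 1) is rerun on the thresholded matrix until all
runs agree, and the agreement-threshold-cluster cycle iterates (cap 100)
if they do not — the standard consensus-clustering construction.

## Rank-based comparison

Nodes are ranked by NOS strength and, separately, by the scalar-weighted
average (rank 1 = highest; ties receive average ranks). The per-node
difference `d_i = rank_scalar_i - rank_nos_i` is z-scored with the sample
SD; with tie-free inputs d sums to zero exactly, so z has mean 0 and SD 1.
Under this sign convention a node (or class) that fares *better* under the
scalar weighting has negative z; `flip_sign = TRUE` flips the presentation
if the opposite orientation is preferred. Medians of z are reported per
functional class (7 Yeo-style labels; VIS and SM unimodal, the rest
transmodal) and per cytoarchitectonic class (7 von Economo-style labels),
along with module-by-class contingency tables for the consensus
partitions.

## The synthetic cohort

No MRI data ship with the package; `generate_cohort_matrices()` plants the
structure the analysis is supposed to find.

* **Edges.** A population template edge exists with probability 0.9 within
  a planted module and 0.1 between modules; each subject retains a template
  edge with probability 0.8. The dropout gives the 50% prevalence rule real
  work: some template edges survive consensus, others do not. The
  inter-subject variability model is an artifact design choice — no
  empirical cohort informs it.
* **Counts.** Streamline counts on present edges are Poisson (mean 20
  within, 2 between modules) truncated to at least 1, with a mean-preserving
  log-normal per-subject rate fluctuation (relative SD 0.1).
* **Scalar weights.** `base + mean(class offsets of the two endpoints) +
  N(0, 0.05)`, clipped to the physiological (0, 3) 1/s envelope. The
  default base is 1.1 1/s; transmodal functional classes carry a +0.05 1/s
  offset, so the rank analysis has a planted transmodal-versus-unimodal
  gradient of known sign to recover. Classes are assigned round-robin and
  are therefore orthogonal to the planted modules.
* **Defaults.** 60 regions, 4 equal modules, 35 subjects.

What the generator does *not* emulate: spatial autocorrelation of cortical
maps, distance-dependent connection probability, hub/rich-club structure
(node strengths are homogeneous by design, so hub counts on synthetic data
are typically zero), scanner noise, and tracking biases. Passing tests on
this cohort therefore demonstrate that the estimators recover what was
planted under honest noise — not that real cortical data behave this way.

## Phantom geometry

`generate_phantom_geometry()` adds a full image-domain phantom: a label
volume of compact spherical regions, a scalar volume, and a tractogram of
arc-shaped streamlines (about 1 mm vertex spacing, small jitter), with
per-pair counts drawn by the same edge model. Region placement and one
corridor arc per region pair are found once by a deterministic repair
search (fixed internal seed sequence, independent of the user seed) that
enforces: corridors pairwise separated outside guard balls around shared
endpoints, corridors clear of non-incident regions, and arc lengths within
the 20–250 mm filter window (at least 72 mm). The scalar volume paints
each realized corridor with its planted value on a constant background,
never within 12 mm of a region centre. These margins guarantee that every
painted voxel belongs to exactly one bundle and that a strict majority of
each streamline's samples take the planted value — so with zero noise the
pooled bundle median equals the planted value *exactly* (nearest-voxel
sampling), a property the tests assert literally. Straight-ish arcs
suffice because corridor curvature is irrelevant to the sampling and
assignment math being exercised. The search is capped at 8 regions
(default 6); larger phantoms would need a different routing scheme, and
the matrices-mode generator covers large-n needs.

## Numerical choices and degenerate inputs

* Louvain ties keep the current community; moves require a strict gain
  (epsilon 1e-12) to avoid floating-point cycling.
* z-Rand returns 0 when the null variance vanishes (degenerate partitions).
* `detect_hubs` with SD 0 returns the empty set; `rank_difference_z` with
  all-zero differences returns all-zero z.
* Matrices are validated symmetric within 1e-9 and repaired to exact
  symmetry by averaging; NOS entries must be integers except for consensus
  medians, which may be half-integers.
* All randomness descends from one master seed through a Lehmer-style
  integer recurrence (`derive_seed`), so any stage can be reproduced in
  isolation; compiled code uses its own mt19937 stream and never touches
  R's RNG.

## Problem sizes used by the shipped checks

The test-suite and the acceptance script run the full pipeline at reduced
but honest scale, chosen so the planted structure is still decisively
recoverable: 60-node, 35-subject cohorts; resolution grids of step 0.25
with 100 Louvain runs per level (the stability statistic is already stable
at 100 runs on these graphs); 50 random graphs of up to 8 nodes for the
exhaustive-search comparison; and 6-region phantoms for the geometry
checks. The full-scale settings (step 0.1, 1,000 runs) remain the
defaults of `gamma_sweep()` and `pipeline_config()`.

## Worked example

```{r example, eval = FALSE}
spec <- phantom_spec()                       # 60 nodes, 4 modules, 35 subjects
co <- generate_cohort_matrices(spec, seed = 1)
cons <- consensus_weights(co, consensus_mask(co, 0.5))
edge_regression(cons$scalar, cons$nos)$r_squared

sw <- gamma_sweep(cons$nos, seq(0.5, 3, 0.25), n_runs = 100, seed = 2)
sw$selected_gamma
rand_index(sw$consensus, co$planted)         # 1 = planted modules recovered

rank_comparison(cons$nos, cons$scalar, co$classes)
```

## Known limitations

* The synthetic cohort is homogeneous by design; effect sizes for the
  class gradient (+0.05 1/s) are planted, not estimated from data.
* Geometry mode is small-scale (up to 8 regions) and uses idealized
  corridors; it validates sampling and assignment code paths, not
  tractography realism.
* The consensus-partition procedure assumes the run ensemble carries a
  dominant signal; adversarial ensembles can hit the iteration cap (an
  error, not a silent fallback).
* Only undirected, non-negative connectomes are supported.
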