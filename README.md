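# myeloconn

Myelin-sensitive weighting and comparison of structural brain connectomes.

Structural connectomes conventionally weight each edge by the number of
tractography streamlines (NOS) between two cortical regions — a quantity
shaped as much by fibre geometry and tracking heuristics as by anatomy. A
myelin-sensitive alternative weights the same edges by a quantitative MRI
scalar sampled along the connecting bundle, typically the longitudinal
relaxation rate R1 = 1/T1 (in 1/s), which tracks myelin content.
`myeloconn` builds both weightings and provides the comparison machinery
used to ask whether they describe the same network organization. It is
aimed at network-neuroscience practitioners who have tractograms,
parcellations and quantitative maps (or who want a fully synthetic test
bed with planted ground truth).

## What it computes

* **Connectome construction** — streamline length filtering (20–250 mm,
  inclusive), endpoint-to-region assignment (containment with a
  nearest-labelled-voxel fallback), scalar sampling along streamlines
  (trilinear or nearest), and paired edge weights: NOS `w_ij` and the
  bundle-pooled median scalar `v_ij`, with a minimum-streamline threshold
  (2, or 5 for robustness) applied to both matrices jointly.
* **Group consensus** — edges kept when present in ≥ 50% of subjects
  (`ceiling(prevalence · n)` rule), weighted by the across-subject median
  over present subjects; plus OLS edge-weight regression between
  weightings.
* **Node metrics** — NOS strength `S_i = Σ_j w_ij`; the scalar-weighted
  average `S_i = Σ_j w_ij v_ij / Σ_j w_ij` (independent of connection
  count); hubs at mean + 2 SD (and 3 SD) of strength.
* **Modular structure** — resolution-scaled modularity
  `Q(γ) = (1/2m) Σ_ij (A_ij − γ k_i k_j / 2m) δ(c_i, c_j)`, maximized by a
  seeded from-scratch Louvain implementation; a γ sweep over 0.5–3 (step
  0.1, 26 levels) with many runs per level; γ selection by partition
  stability (mean pairwise z-scored Rand coefficient under the
  hypergeometric null); and a consensus partition via agreement-matrix
  thresholding against a label-permutation null.
* **Rank-based comparison** — per-node rank differences between the two
  weightings, z-scored, with medians per functional (Yeo-style) and
  cytoarchitectonic (von Economo-style) class and module-by-class
  composition tables.
* **Synthetic phantoms** — cohorts of paired NOS/scalar matrices with
  planted modules, planted transmodal scalar elevation, and inter-subject
  noise; optionally full geometry (label volume, scalar volume, TCK/TRK
  tractogram) with exact ground truth.

File formats: TCK and TRK tractograms, NIfTI volumes (via RNifti), dense
CSV matrices, JSON results. A thin CLI (`inst/cli/myeloconn`) exposes the
stages as subcommands (`simulate`, `build`, `consensus`, `metrics`,
`communities`, `ranks`, `composition`, `run`).

## Worked example

```r
library(myeloconn)

spec <- phantom_spec()                    # 60 nodes, 4 planted modules, 35 subjects
co   <- generate_cohort_matrices(spec, seed = 1)
cons <- consensus_weights(co, consensus_mask(co, 0.5))

edge_regression(cons$scalar, cons$nos)$r_squared
#> R^2 = 0.003452 over 522 edges

sw <- gamma_sweep(cons$nos, seq(0.5, 3, 0.25), n_runs = 100, seed = 2)
sw
#> <sweep_result> 11 resolutions in [0.5, 3], 100 runs each
#>   selected gamma = 0.5 (stability), mean Q = 0.8374
#>   consensus partition: 4 modules
rand_index(sw$consensus, co$planted)
#> [1] 1

rank_comparison(cons$nos, cons$scalar, co$classes)
#> <rank_comparison> 60 nodes (sign: negative = better scalar rank)
#> functional class medians:
#>     DA    DMN     FP    LIM     SM     VA    VIS
#>  0.021 -0.617 -0.668 -0.730  0.843  0.041  0.514
```

Reading the output: the NOS and scalar edge weights share almost no
variance (R² ≈ 0.003 — they carry different information by construction);
the stability-selected resolution recovers the four planted modules
exactly (pair-counting agreement 1); and the planted +0.05 1/s transmodal
elevation shows up as negative rank-difference medians for the transmodal
classes (DMN, FP, LIM) — they rank better under the scalar weighting —
and positive medians for the unimodal SM and VIS.

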