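---
title: "Trajectory Profile Clustering: model, choices, and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trajectory Profile Clustering: model, choices, and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trajpc)
```

## The model

Trajectory Profile Clustering (TPC) treats a longitudinal cohort as a stack
of patient–variable bipartite graphs, one per visit, and asks which patients
have similar *trajectories* — not merely similar severity at one visit. The
pipeline is deliberately simple and fully deterministic given a seed:

1. every continuous variable is aligned with disease progression by its
   direction `d_v` (so higher always means worse);
2. values are discretized against the **training-population baseline
   median** `θ_v`: patient `i`'s binary profile is
   `T_i[v,t] = 1(Y[i,v,t] > θ_v)`. Gender enters as a 1/0 row and each
   genotype locus as a one-hot block, replicated over visits;
3. pairwise agreement counts `P_ij = Σ_{v,t} w_vt 1(T_i = T_j)` define a
   dense weighted patient network;
4. Louvain community detection maximizes weighted Newman–Girvan modularity
   on that network; the number of subtypes is emergent;
5. each subtype is summarized by its normalized average profile
   `S_l[v,t] = Σ_{i∈C_l} T_i[v,t] / (N_l U_v0)` with population baseline
   normalizer `U_v0`, and by the unnormalized "affected fraction";
6. held-out patients are profiled with the *training* thresholds and
   assigned, per timepoint, to the subtype minimizing
   `Σ_v (T[v,t] − S_l[v,t])²`; the baseline-vs-final concordance over test
   patients is the prediction accuracy.

The key assumptions are: (a) severity relative to the cohort's baseline
median carries the subtype signal, so absolute scale values and their units
are irrelevant after thresholding; (b) each variable-timepoint cell is
informative on its own and cells are exchangeable under the (default unit)
weight scheme; (c) subtype structure is expressible as assortative
communities of the agreement network.

## Tunable parameters

| Parameter | Default | Meaning and rationale |
|---|---|---|
| `test_fraction` | 0.2 | held-out share; half-up rounding gives 39/155 on a 194-patient cohort |
| `min_size` | 10 patients | communities smaller than this are kept in the partition but excluded from reporting and from the prediction reference set |
| `weights` (`w_vt`) | all 1 | unit weights make `P_ij` a plain agreement count; unequal weights let domains be emphasized |
| `static_count_once` | `FALSE` | static columns (gender, genotype, static age) are replicated over the M visits and hence counted M times in `P`; setting this restricts them to baseline for sensitivity analysis |
| `distance_profile` | `"normalized"` | prediction distances compare the binary profile against the normalized `S` (entries can exceed 1), exactly as defined; `"affected_fraction"` compares against the unnormalized fraction that the heatmaps display |
| `seed` | caller-supplied | controls the Louvain sweep order, cohort splits and synthetic generation; all results are reproducible bit-exactly under a fixed seed |
| Louvain resolution | 1 (fixed) | plain Newman–Girvan modularity is maximized; no resolution scanning |

## Numerical and design choices

* **Ties at the threshold score 0.** Discretization uses strict `>`; with
  untied baselines this forces the training baseline affected fraction to
  `⌊N/2⌋/N` per continuous variable (the "close to 0.5" population panel).
  No tolerance band is applied.
* **Medians** use the mean-of-central-order-statistics convention for even
  sample sizes; thresholds are computed once on training data, frozen into
  the model artifact, and reused verbatim for test patients.
* **Genotype encoding** is one binary column per diploid class (three per
  biallelic SNP) rather than a single carrier flag: the three-class
  information is what subtype genotype panels interpret, and a carrier flag
  is a linear function of the one-hot block anyway.
* **Self-loops are excluded** from the clustering graph (diagonal of `P` set
  to 0): self-agreement is the constant `Σ w` and carries no community
  information. Modularity is defined on the off-diagonal graph.
* **`U_v0 = 0` columns** (no training patient affected at baseline) make
  `S` undefined for that column; such columns are flagged and excluded from
  prediction distances for *all* subtypes symmetrically.
* **Tie-breaks.** Prediction ties go to the lowest community id and are
  flagged; community relabeling after Louvain is by decreasing size with
  ties by first-encountered member; confidence ranking is a stable sort.
* **Louvain determinism.** The node sweep order is randomized under the
  caller's seed (via R's RNG), so a fixed seed yields identical partitions.
  Dense agreement networks have small absolute modularity (every pair
  agrees on many cells by chance); the degree-preserving null model inside
  `Q` absorbs that offset, and the test suite verifies that the attained
  `Q` matches exhaustive partition enumeration on small graphs.
* **Distances** omit the square root (argmin-equivalent) and sum over every
  profile column present in the fitted model — clinical, demographic and
  genotype alike — since the assignment rule carries no column restriction.
* **Statistics on raw values.** Subtype contrasts use raw (untransformed,
  undirected) values for medians and tests, reporting each variable's
  direction alongside; unadjusted p-values are reported and flagged against
  `α/n_c` with `n_c = n_p(V_d + 2V_e)`. The exact Mann–Whitney distribution
  is used up to combined n = 20 without ties, otherwise the tie-corrected
  normal approximation; the method used is recorded per row. A fully tied
  comparison (zero rank variance) is reported as p = 1.

## What the synthetic generator emulates — and what it does not

`ppmi_like_spec()` emulates the *structure* of a Parkinson's progression
cohort: 194 patients, five yearly visits, 17 evolving clinical scales in six
domains with their conventional severity directions, static age, gender, and
four biallelic SNP loci (23 variables, 31 profile columns after one-hot
expansion). Three planted subtypes follow the qualitative shapes of
published descriptions: *mild* (affected fractions 0.35→0.25 everywhere,
average demographics), *mixed* (motor 0.70→0.85 and non-motor 0.75→0.90 but
cognition flat at 0.25; younger, 38% male), and *severe* (motor and
cognition 0.70→0.90, non-motor near average at 0.45→0.55; older, 80% male),
with mixing proportions 0.40/0.35/0.25 and subtype-specific genotype
frequencies at high minor-allele loci.

The generative model is a probit-spaced latent Gaussian: a subtype-`k`
member's directed value is `qnorm(p[k,v,t]) + σ·ε` with `ε ~ N(0,1)`, so the
probability of exceeding the population threshold is `pnorm(qnorm(p)/σ)` —
exactly the target `p` at the reference noise `σ = 1`, and shrinking toward
0.5 as `σ` grows, which is the axis along which recovery degrades in the
noise-sweep tests. All randomness flows from a single seeded generator with
a fixed draw order (a per-patient substream scheme would add complexity
without changing the reproducibility guarantee).

What the generator does **not** emulate: real scale marginals (integer
scores, floors/ceilings, skew), within-domain correlation beyond subtype
membership, visit-to-visit autocorrelation of the noise, informative
dropout, or genotype–phenotype coupling. Passing recovery tests therefore
shows the pipeline recovers planted threshold-exceedance structure under
Gaussian noise — not that any particular clinical dataset contains three
subtypes.

## Problem sizes used by the test suite

Oracle checks run at deliberately small sizes where exhaustive enumeration
is feasible: agreement matrices on up to 20 patients against an explicit
double loop (100 instances), Louvain against all set partitions of up to 8
nodes (20 graphs, Bell(8) = 4140 partitions each), exact Mann–Whitney
against all `C(n, n_a)` group assignments and Fisher against hypergeometric
enumeration. Recovery checks use the full reference geometry (194 patients,
20 seeds, a five-point noise grid), and null calibration uses 1000
replicates of a compact three-group design (36 patients, two evolving
scales, age and gender) — sizes chosen so the planted effects, not runtime,
are what the assertions measure.

## Known limitations

* Thresholding at the baseline median is relative: a variable can appear to
  "progress" sharply even when absolute impairment is mild (insensitive
  scales in early disease), and fluctuations of baseline values exactly at
  the median perturb the 0.5 population panel.
* Louvain is a greedy heuristic; on near-degenerate modularity landscapes
  different seeds can return different local optima. The seed is stored in
  the model artifact, and small-graph optimality is verified in tests, but
  global optimality at cohort scale is not guaranteed.
* Modularity maximization carries the usual resolution limit; very small
  true subtypes may be absorbed (and are in any case excluded below
  `min_size`).
* Equal cell weighting means a block of many correlated columns (e.g. many
  SNPs) would dominate `P`; the weight scheme exists precisely because no
  principled default weighting is claimed.
* Complete-case filtering is the only missing-data policy; no imputation is
  offered.
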