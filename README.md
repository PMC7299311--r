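# trajpc — Trajectory Profile Clustering for longitudinal disease subtyping

Chronic progressive diseases such as Parkinson's disease are heterogeneous:
patients differ not only in how severely affected they are at any one visit,
but in how their many clinical variables evolve over years. `trajpc`
implements Trajectory Profile Clustering (TPC), a network-based method that

1. **identifies disease subtypes** by clustering patients whose multi-year,
   multi-variable trajectories are similar, and
2. **predicts an unseen patient's future subtype** from baseline data alone.

It is aimed at researchers working with longitudinal cohort studies (yearly
clinical scale scores, demographics, optional genotype calls) who want
data-driven, progression-aware subtypes plus an honest prediction metric.

## The method

Let `X[i,v,t]` be patient `i`'s value of variable `v` at timepoint `t`
(an N × V × M array; `t = 0` is baseline).

1. **Direction alignment.** Each continuous variable has a direction
   `d_v ∈ {+1, −1}` (+1 when a higher score means greater severity); set
   `Y[i,v,t] = d_v · X[i,v,t]`. Binary and genotype variables pass through.
2. **Binary trajectory profiles.** With `θ_v` the median *baseline* value of
   `v` in the training data, each patient gets a binary profile matrix
   `T_i[v,t] = 1 if Y[i,v,t] > θ_v, else 0`. Gender contributes a 1/0 row
   (1 = male); each genotype locus contributes a one-hot row per diploid
   class (e.g. CC/CT/TT), replicated across timepoints.
3. **Patient–patient network.** The similarity of patients `i` and `j` is
   the (optionally weighted) count of agreeing profile cells,
   `P_ij = Σ_{v,t} w_vt · 1(T_i[v,t] = T_j[v,t])`, a dense symmetric
   matrix with zero diagonal.
4. **Subtype detection.** Louvain community detection maximizes the
   weighted Newman–Girvan modularity `Q` of `P`; the number of subtypes is
   emergent, and communities with fewer than 10 patients are excluded from
   reporting and prediction.
5. **Subtype profiles.** Each subtype is summarized by
   `S_l[v,t] = Σ_{i∈C_l} T_i[v,t] / (N_l · U_v0)`, the member-average
   profile normalized by the population baseline mean `U_v0`; the
   unnormalized member average (the "affected fraction") is what the
   heatmap reports render.
6. **Prediction.** A held-out patient is assigned to the subtype minimizing
   the squared distance `d_t(i,l) = Σ_v (T_i[v,t] − S_l[v,t])²` at
   baseline, and again at the final timepoint; prediction accuracy is the
   fraction of test patients whose two assignments agree.

A planted-subtype synthetic cohort generator (`ppmi_like_spec()`,
`generate_cohort()`) and subtype-contrast statistics (Mann–Whitney U,
Fisher exact, Bonferroni budget `n_c = n_p(V_d + 2V_e)`) are included.

## Worked example

```r
library(trajpc)

spec  <- ppmi_like_spec()                       # 194 patients, 5 visits, 3 planted subtypes
sim   <- generate_cohort(spec, seed = 1)
split <- split_cohort(sim$cohort, test_fraction = 0.2, seed = 1)  # 155 train / 39 test

model <- fit_tpc(split$train, seed = 1)
#> 3 communities (3 retained at min_size 10), Q = 0.0362
print(model$partition)
#> <subtype_partition> 3 communities (Q = 0.0362, seed 1)
#>   sizes: 1:65, 2:58, 3:32

report <- predict_tpc(model, split$test)
print(report)
#> <prediction_report> 39 test patients, accuracy 89.7%

bonferroni_budget(n_p = 3, V_d = 2, V_e = 16)
#> <comparison_budget> n_c = 102 comparisons, alpha_adjusted = 0.00049
```

Three subtypes are recovered from the training network (modularity is small
in absolute terms because the agreement graph is dense — every pair of
patients agrees on many cells by chance — but the partition is the
modularity optimum). Of the 39 held-out patients, 89.7% are assigned to the
same subtype at year 4 as predicted from their baseline visit alone.
`report_tpc(model, out_dir)` renders per-subtype affected-fraction heatmaps
(the population panel's baseline row sits at ≈ 0.5 by construction of the
median thresholds), and `compare_subtypes()` reproduces the
raw-data-median + rank-test contrast table with Bonferroni flagging.

A thin command-line interface wraps the same functions:

```sh
Rscript inst/cli/trajpc.R simulate --out sim --n 194 --seed 1
Rscript inst/cli/trajpc.R fit --cohort sim/cohort.csv --metadata sim/metadata.json --out model.json
Rscript inst/cli/trajpc.R predict --model model.json --cohort sim/cohort.csv \
    --metadata sim/metadata.json --out predictions.csv
```

Cohort files use a long-format CSV plus a variable-metadata JSON; the schema
is documented in `inst/extdata/cohort-schema.md`.

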