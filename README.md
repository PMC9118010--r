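# morbclust

Multimorbidity — several chronic conditions coexisting in one patient — is a
major driver of health-service use and cost, but services are mostly planned
disease by disease. `morbclust` takes a flat table of visit records coded in
ICD-10 and finds groups of diseases that tend to occur in the same patients,
so that planners and epidemiologists can see which conditions travel
together and what each group costs.

The pipeline:

1. **Filter** visit-diagnosis rows to adults (≥ 18 years) with a diagnosis in
   an included ICD-10 block (3-character ranges such as `I20-I25`); symptom
   codes (R), external causes (V–Y), service contacts (Z) and special codes
   (U) are dropped.
2. **Network.** For every pair of blocks *x*, *y*, compute the relative risk
   from patient-level prevalence,

   RR(x,y) = p(xy) / (p(x) p(y)) = P_xy · N / (P_x · P_y),

   where `P_x` is the number of patients ever carrying a diagnosis in block
   *x* and `P_xy` the number carrying both. Pairs with RR ≥ 1 and at least 10
   patients in common become edges; edge weights are RR mapped into (0,1) by
   the sigmoid `w = rr² / (rr² + c²)` (half-point `c = 5`) so that extreme
   RR values cannot dominate the clustering.
3. **Cluster.** Partition the network into *k* clusters minimizing the
   inverse internal weight (IIW)

   cost = (1/k) · Σᵢ M / Wᵢ,

   where `Wᵢ` is the edge weight captured inside cluster *i* and `M` the
   total graph weight. Optimization uses a sequential k-means-style local
   search on the graph (the **K-algorithm**) wrapped in a randomized
   merge/split search (the **M-algorithm**) that escapes local minima;
   the number of clusters can be chosen by a silhouette sweep.
4. **Summarize.** Per-cluster demographics, annual patient/visit counts,
   annual costs, cost per visit and per patient, the matrix of
   inter-cluster links with RR > 2, and annual cost-share trends.

A synthetic cohort generator with planted disease groups makes every stage
testable without access to registry data, and an exhaustive-enumeration
oracle certifies the clustering heuristic on small graphs.

## Worked example

```r
library(morbclust)
gen  <- generate_cohort(cohort_config(n_patients = 2000, seed = 7))
kept <- filter_visits(gen$records)$kept
net  <- build_network(pair_counts(build_patient_index(kept)))
net
#> Multimorbidity network: 40 diagnosis blocks, 180 edges, 2000 patients
#>   rr range: 2.567 - 3.279

part <- m_algorithm(net, k = 4, repeats = 500, seed = 7)
part
#> Graph partition: k = 4 , IIW cost = 4.000984
#> cluster
#>  1  2  3  4
#> 10 10 10 10

adjusted_rand(part$assign, gen$true_partition[net$nodes])
#> [1] 1
```

The cohort plants 4 disease groups over 40 ICD-10 blocks; the network keeps
the 180 within-group pairs (all with RR ≈ 2.6–3.3, i.e. clearly above
chance), and the clustering recovers the planted groups exactly (adjusted
Rand index 1). `summarize_clusters(kept, part$assign, n_years = 4)` then
reports, per cluster, the annual mean number of distinct patients, percent
women, median age, percent aged ≥ 70, annual visits and costs, cost per
visit (whole-period mean) and annual cost per patient:

```
  cluster n_patients_annual_mean pct_women median_age pct_age_ge70 n_visits_annual_mean total_cost_annual_mean cost_per_visit cost_per_patient
1       1                    237      59.2         52         19.4                  582                 315041            542             1328
2       2                    240      58.6         56         21.9                  609                 328979            540             1371
...
```

`run_pipeline()` chains all stages from a single (YAML-able) configuration
and writes per-stage artifacts plus a manifest;
`inst/scripts/pipeline.R` exposes the same stages as shell subcommands
(`simulate`, `network`, `cluster`, `summarize`, `run-all`).

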