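---
title: "Multimorbidity networks and IIW graph clustering: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimorbidity networks and IIW graph clustering: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morbclust)
```

## The model

`morbclust` groups *diagnoses*, not patients: every ICD-10 block belongs to
exactly one cluster, while a patient may appear in several clusters. The
analysis has three statistical ingredients.

**Patient-level prevalence.** All counting is per patient over the whole
study window. `P_x` is the number of distinct patients ever recorded with a
diagnosis in block `x`; repeat visits add nothing. This makes the derived
quantities invariant under replication of the cohort and insensitive to
visit frequency, which varies with care organization rather than morbidity.

**Relative risk.** For blocks `x` and `y`,

$$\mathrm{RR}(x,y) = \frac{p(xy)}{p(x)\,p(y)} = \frac{P_{xy} N}{P_x P_y},$$

the observed co-occurrence probability relative to the expectation under
independence. RR = 1 is exact independence; RR > 1 indicates association.
Edges enter the network when RR ≥ 1.0 **and** at least 10 patients carry
both diagnoses (both bounds inclusive). The patient-count floor guards the
well-known instability of RR for rare pairs: with `P_xy` in single digits a
single patient can move RR by tens of percent.

**Weight normalization.** Most RR values fall between 0.5 and 5, but the
tail reaches into the hundreds, and a sum-based clustering cost would be
dominated by a handful of extreme edges. Weights are therefore

$$w = \frac{\mathrm{rr}^h}{\mathrm{rr}^h + c^h},$$

a symmetric sigmoid with half-point `c` (default 5, the upper edge of the
bulk of the RR distribution) and exponent `h` (default 2). It is strictly
increasing — the RR ranking of edges is preserved exactly — maps 0 to 0 and
∞ to 1, and compresses everything above ~3·c into a narrow band near 1.
Both parameters are exposed (`build_network(half_point=, steepness=)`).

## The clustering cost

For a partition into `k` clusters with internal weights `W_i` (sum of edge
weights with both endpoints in cluster `i`) and total graph weight `M`,

$$\mathrm{IIW} = \frac{1}{k} \sum_{i=1}^{k} \frac{M}{W_i},$$

minimized. Because `1/W` is convex, at fixed total internal weight the sum
is minimal when the `W_i` are equal, so the cost intrinsically favours
clusters of balanced weight — in practice, of similar size — which is what
one wants when the clusters are to be inspected by hand. The constant `M`
and the `1/k` prefactor do not change the minimizer; they make values
comparable across graphs and across `k`.

Edge cases are handled as follows:

* A cluster with `W_i = 0` that contains any node with positive strength
  makes the cost `+Inf`: the optimum can never contain a weight-starved
  cluster.
* A cluster consisting solely of isolated nodes (zero incident weight) is
  excluded from the mean, with a warning. Isolated blocks are kept as nodes
  by default (`keep_isolated = TRUE`) so that every diagnosis receives a
  label; since they carry no weight, their placement cannot affect any
  `W_i`, and excluding their clusters from the mean is the only consistent
  convention.
* Inside the optimizer only, zero weights are clamped to `1e-9` instead of
  `Inf`. A random initialization can start with several zero-weight
  clusters; with a literal `Inf` the search would see no gradient between
  "two broken clusters" and "one broken cluster". The clamped surrogate is
  enormous but finite and strictly decreasing in the number of repaired
  clusters, and it coincides exactly with the true cost on every partition
  whose contributing clusters have positive weight. Reported costs are
  always the true IIW.

## The K- and M-algorithms

The **K-algorithm** is sequential k-means transplanted to graphs: nodes are
visited in random order, and each node is reassigned to the cluster that
most improves the cost, with the cluster weights updated immediately so
later decisions in the same pass see the effect (batch updates are known to
oscillate). Moves that would empty a cluster are skipped. A node moves only
on *strict* improvement (relative tolerance `1e-12`) — this is the
tie-break rule, and it prevents infinite oscillation between equal-cost
states. Passes repeat until one completes without a move; a safety cap of
100 passes returns the current state with a warning (never observed to
trigger on converging instances).

The move evaluation is incremental: for node `v`, the weight it contributes
to each cluster is accumulated from its incident edges once, and each
candidate reassignment costs O(k). Correctness is defined against full
recomputation: the test suite asserts that the cost reported after a run
equals `iiw_cost()` recomputed from scratch to within 1e-9.

Local search alone gets trapped. The **M-algorithm** wraps it: starting
from a tuned random `k`-labelling, each round merges two distinct random
clusters, splits one random cluster (size ≥ 2) by a uniform random
bipartition with both sides non-empty, re-tunes with the K-algorithm, and
accepts the result only if the cost strictly improves. The uniform
bipartition is deliberately crude — the K-algorithm immediately repairs it,
and cruder splits explore more of the solution space per round. The default
is 20,000 rounds, appropriate for a final production run on a ~200-node
network (minutes of CPU); the test suite and examples use 30–500 rounds,
which already attain the exhaustive optimum on every ≤ 12-node instance
tried.

Randomness comes from R's global RNG, consumed in a documented order
(initial labelling; then per round: merge choice, split choice,
bipartition, K-algorithm shuffles), so `m_algorithm(net, k, seed = s)` is
byte-reproducible.

**Oracle.** `exhaustive_best_partition()` enumerates all partitions of the
nodes into exactly `k` non-empty clusters via restricted growth strings
(one representative per labelling up to label permutation) and returns a
global minimizer. The count is the Stirling number S(n, k) — 86,526 at
n = 12, k = 3 — so the oracle is capped at 13 nodes and exists purely to
certify the heuristic in tests.

## Choosing k

`select_k_silhouette()` scores each `k` in a sweep by the mean silhouette
under the graph dissimilarity `d(u,v) = 1 − w(u,v)` for adjacent pairs and
`d = 1` for non-adjacent pairs (`d(u,u) = 0`); nodes in singleton clusters
score 0, the standard convention. This dissimilarity is the natural
complement of the sigmoid weight, but it is one choice among several — the
silhouette's absolute level is not comparable across dissimilarities, only
the argmax is used. The conventional sweep range for a ~200-block network
is 5–25; on the 4-group synthetic cohort a 2–8 sweep selects k = 4.

A practical alternative to the sweep is fixing `k` so that the expected
cluster size `N/k` is convenient for manual review; with 205 blocks and
k = 15 that is ≈ 13.7 blocks per cluster.

## Cluster summaries

`summarize_clusters()` follows register-reporting conventions, and the
conventions matter more than the arithmetic:

* A visit-diagnosis row contributes to exactly the cluster containing its
  block; a patient (and a visit) can therefore appear in several clusters.
* Patient counts, visit counts and total costs are **annual means** (totals
  divided by `n_years`); **cost per visit** is the whole-period mean;
  **cost per patient** divides annual cost by the annual mean number of
  distinct patients.
* The input is one row per visit-diagnosis, so a visit carrying several
  diagnoses contributes its cost once per diagnosis row. Visit *counts*
  deduplicate by (patient, date, cluster) by default
  (`dedup_visits = FALSE` counts raw rows; conservation tests use that
  mode, where cluster visit counts sum exactly to the kept rows).
* Median age is over distinct patients (age at first in-window record),
  not over visits, which would overweight frequent attenders.

`intercluster_links()` counts edges with RR **strictly** above a threshold
(default 2.0) between each cluster pair; `cost_trends()` reports each
cluster's share of each year's total cost, columns summing to 100%.

## The synthetic cohort

The generator exists because nationwide registry data cannot be shipped.
Each patient draws a latent group from `group_prob`; their distinct
diagnosis count is Poisson with a gender-specific mean; blocks are sampled
without replacement with probability proportional to `boost` (default 20)
on the patient's own group and 1 elsewhere. This group-conditional mixture
was chosen over pairwise copulas because it directly induces the
block-level RR structure that the clustering assumes, with one
interpretable knob: `boost = 1` is exact no-structure (within- and
between-group RR equal in expectation), and separation grows monotonically
with it.

Defaults emulate a nationwide adult register: 54% women; mean distinct
diagnoses 6.6 (women) and 5.4 (men); 1.6 diagnoses per visit (visit sizes
`1 + Poisson(0.6)`); ages normal with median 54, truncated to 18–100,
putting roughly a fifth of patients over 70; visits uniform over 2015–2018;
per-diagnosis costs lognormal(meanlog 5.5, sdlog 1.0) €, a deliberately
heavy tail. The default cohort size is 5,000 patients over 40 blocks in 4
planted groups — large enough that every within-group pair clears the
10-patient edge floor, small enough to regenerate in under a second.

What the generator does **not** emulate: real ICD-10 epidemiology (true
prevalences, age- and sex-specific disease profiles), care-type structure,
coding practice drift over years, or overlapping/nested disease groups.
Passing the recovery tests therefore shows that the pipeline recovers
planted block-level co-occurrence structure under realistic marginals — it
does not validate any clinical claim about real registries.

## Numerical choices and problem sizes

* Strict-improvement threshold `1e-12` (relative) in the K-algorithm;
  oracle comparisons at `1e-9`; zero-weight clamp `1e-9` in the optimizer.
* Edge lists are written with 17 significant digits so round-trips are
  exact at double precision.
* Test and example sizes: oracle certification on 20 random graphs of 8–12
  nodes (k ∈ {2, 3}, 200 merge/split rounds); recovery on the default
  5,000-patient cohort with 10 clustering seeds; generator calibration over
  5 seeds. These sizes keep the whole suite around half a minute while
  leaving the certified properties at full strength.

## Limitations

Every diagnosis is forced into exactly one cluster, including blocks only
weakly tied to their cluster; outlier pre-filtering would be a natural
extension. The silhouette dissimilarity treats all non-adjacent pairs as
maximally distant, which flattens long-range structure. The IIW cost
favours weight-balanced clusters by construction — on networks with
genuinely unbalanced community sizes that is a bias, not a feature. And the
shipped block table is the standard ICD-10 chapter/block list; registers
with local aggregations should supply their own table
(`load_block_table(path)`).
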