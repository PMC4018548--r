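---
title: "Statistical parametric networks and density-aware topological metrics"
author: "spnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical parametric networks and density-aware topological metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spnet)
```

## The problem

Functional connectivity studies produce one association matrix per subject
and experimental condition: an $N_V \times N_V$ matrix of inter-regional
correlations. Comparing such families of networks raises two entangled
problems. First, summarizing a *population* of networks into one graph is
ill-posed: thresholding is an elementwise indicator and hence non-linear, so
the average of thresholded matrices is not the thresholded average matrix,
and neither is an inferential summary. Second, essentially every popular
topological metric — global efficiency, modularity, and their weighted
versions — is strongly driven by wiring density (the number of edges, or the
mean edge weight), so topological comparisons between groups that differ in
density mostly measure the density difference.

`spnet` addresses the first problem with *statistical parametric networks*
(SPNs): summary graphs whose edges (or nodes) are the ones passing a
mass-univariate statistical test with multiple-testing correction, by
analogy with statistical parametric mapping. It addresses the second with
*density-aware* metrics — reporting weighted density alongside topology, and
integrating metrics over all achievable densities, which provably removes
any monotone reweighting from the comparison — plus a simulation engine that
demonstrates how strongly greedy modularity depends on edge count and
topological randomness.

## Data model

The full dataset is an $n \times J$ array $R = (R_{ij})$ of correlation
matrices (subject $i$, condition $j$), held by `correlation_dataset()` with
ordered condition labels: the order encodes the experimental gradient (e.g.,
increasing working-memory load). Edges of the saturated graph are indexed in
the lexicographic order of `edge_pairs()`; there are $N_E = N_V(N_V-1)/2$ of
them. Node-level data (time-averaged regional signals $y^v_{ij}$) live in a
`node_signal_table()`. Correlations are Fisher z-transformed
($z = \operatorname{atanh} r$) before any edge-level inference, which
stabilizes variances and makes additive condition effects a natural model.

## Mean SPNs

`mean_spn()` summarizes one condition's average connectivity. For each edge
$e$, the statistic compares the edge's mean Fisher-z correlation with the
grand sample mean by a z-test,
$$ t^e = \frac{\bar z^e - \bar{\bar z}}{\mathrm{sd}(z) / \sqrt{n}}, $$
with the grand mean and grand standard deviation computed over all edges and
subjects within the condition. Two conventions were genuinely open:

* **Sidedness.** The test is one-sided (upper tail): a mean SPN answers
  "which edges are more strongly connected than average", and a two-sided
  version would include edges for being unusually *weak*, which is not what
  the summary graph is meant to show.
* **Scope of the grand standard deviation.** The default pools all
  subject-level z values (`sd_scope = "values"`); computing it over edge-wise
  means (`sd_scope = "edge_means"`) is also defensible and available as a
  switch, since the two differ by the within-edge sampling noise.

A dataset in which every value is identical has zero grand standard
deviation; this is reported as a "degenerate dataset" error rather than
producing infinities.

## Differential SPNs

`differential_spn()` asks which edges changed across conditions. Each edge's
$n \times J$ matrix of z values is fitted with the within-subject model
$$ z^e_{ij} = \mu + s_i + \beta_j + \varepsilon_{ij}, $$
and the omnibus F-test for the condition factor, with
$(J-1, (n-1)(J-1))$ degrees of freedom, decides inclusion after
multiple-testing correction across all $N_E$ edges jointly. For the balanced
complete designs the package accepts, this fixed-effects fit is exactly the
random-intercept (Laird–Ware) mixed model with the subject intercepts
profiled out, so nothing is lost by avoiding an iterative REML fit — and the
closed-form sums of squares vectorize over all edges at once, which is what
makes the Monte-Carlo calibration studies below affordable. Incomplete
subject-by-condition designs are rejected, not imputed.

Significant edges are assigned to the upweighted network SPN$^+$ or the
downweighted network SPN$^-$ by the sign of the largest-magnitude condition
coefficient (reference-coded condition means). That rule is stated for nodes
in the underlying methodology and extended to edges here for consistency. It
presumes the conditions form a monotone experimental gradient; when a
significant element has coefficients of both signs the package warns rather
than silently picking a side. `node_differential_spn()` is the same model on
raw node signals (no Fisher transform), corrected across the $N_V$ nodes.

Correction is Benjamini–Hochberg FDR at base rate $\alpha_0 = 0.05$ by
default; `none` and `bonferroni` are available (uncorrected thresholds at
$p = 0.01$ are sometimes used for visualization-oriented differential
networks). Correction is applied once per SPN build, not separately within
SPN$^+$ and SPN$^-$.

## Topological metrics

**Global efficiency.** $E(G) = \frac{1}{N_V(N_V-1)} \sum_{i \ne j}
d_{ij}^{-1}$, with $1/\infty = 0$, so it is defined for disconnected graphs;
it equals 1 on complete graphs and 0 on empty ones.

**Weighted metrics.** Weighted shortest paths need a weight-to-length map,
which the efficiency literature leaves implicit; the package uses the
Latora–Marchiori convention, length $= 1/w$. This choice makes the weighted
and unweighted formulas consistent (a uniform-weight complete graph has
$E_W$ equal to its weight) and underlies the degeneracy result: whenever
every positive-weight edge is itself a weighted shortest path between its
endpoints — checkable with `direct_path_condition_holds()`, and guaranteed
on complete graphs with $w_{max} \le 2\,w_{min}$ — the weighted global
efficiency *equals* the weighted density $K_W$ (the mean off-diagonal
weight, also called weighted cost). In that regime, which includes many real
correlation matrices, reporting $E_W$ adds nothing beyond $K_W$. Negative
weights are rejected by the weighted path metrics: silently coercing them
(absolute value? truncation?) would hide a modeling decision the caller
should make explicitly. Thresholding, by contrast, offers a `signed`
(default) and an `absolute` mode.

**Density-integrated metrics.** On $N_V$ vertices the wiring density only
takes the $N_E + 1$ values $m / N_E$, so density is a discrete random
variable $K$ and the density-integrated metric
$$ E_K(G) = \sum_k p(k)\, E(\gamma(G, k)) $$
is an exact finite sum — no quadrature. Here $\gamma(G, k)$ retains the
$\lfloor k N_E \rfloor$ top-ranked edges; because this is rank-based, $E_K$
is invariant under *any* strictly monotone elementwise transform of a
tie-free weight matrix (scaling, powers, `log1p`, rank replacement). That
invariance is the operational meaning of "comparing topology while
controlling for monotone differences in connectivity strength", and it is
tested bit-for-bit. The default density distribution is uniform over the
full achievable range; restricted ranges (`k_min`, `k_max`) mirror the
common practice of integrating over a plausible density window only.

## Numerical choices

* Thresholds are strict ($w > \tau$), so $\tau = 1$ on correlations yields
  an empty graph.
* Density thresholding keeps $\lfloor k N_E \rfloor$ edges (density never
  exceeds $k$) and breaks ties deterministically (weight descending, then
  lexicographic edge order). Ties break the monotone-invariance guarantee,
  so their presence triggers a warning.
* Matrix input is symmetrized by averaging when the asymmetry is at most
  $10^{-4}$ (silently below $10^{-8}$, with a warning above) and rejected
  beyond that; diagonals are forced to zero.
* Degenerate ANOVA inputs: constant responses give $F = 0$, $p = 1$, sign 0;
  zero residual variance with a real condition effect gives $F = \infty$,
  $p = 0$.
* Matrix files are written with 17 significant digits so write/read round
  trips are exact to machine precision.
* Module ids in partitions are contiguous from 1 (R convention).

## The modularity-versus-density experiment

`run_modularity_experiment()` sweeps graph ensembles — nearest-neighbor ring
lattices, optionally randomly rewired, and uniform $G(n, m)$ random graphs —
over edge counts and rewiring counts, detecting communities with greedy
(Clauset–Newman–Moore) modularity maximization and recording module counts.
Design choices that were genuinely open:

* **Rewiring semantics.** One rewiring step detaches a uniformly chosen
  endpoint of a uniformly chosen edge and reattaches it to a uniform random
  vertex, resampling on self-loops and duplicates. This conserves the edge
  count (the stated invariant) but not the degree sequence; a double-edge
  swap would conserve both, which is more than is asked.
* **Lattice degree and edge matching.** The classical ring lattice only
  realizes edge counts $n d / 2$ for even $d$. `nearest_neighbor_graph(n, m)`
  generalizes it to arbitrary $m$ by keeping the $m$ saturated edges with the
  smallest ring distance, so the lattice and random ensembles can be matched
  edge-for-edge; it reduces exactly to `ring_lattice()` when $m = nd/2$. The
  default lattice degree is 4, the standard small-world baseline.
* **Partition reported.** The agglomeration dendrogram is cut at the maximal
  modularity encountered (not at the final full merge); isolated vertices
  count as singleton modules.
* **Random ensemble.** $G(n, m)$ — uniform given the edge count — since only
  the edge count is controlled in the comparison.
* **Reproducibility.** Every (ensemble, edges, rewires) cell draws its own
  substream seed from the master seed, so cells are independently
  reproducible and the whole table is bit-identical across runs.

On 112-vertex graphs the module count rises steeply with rewiring at a fixed
edge count and falls as edges are added, for lattices and random graphs
alike — the quantitative face of the warning that modularity comparisons
between families differing in density mostly reflect the density
difference. Dense deterministic lattices plateau (e.g., 600 and 1200 edges
both yield exactly 3 modules), so the trend is asserted by one-sided rank
tests across the sweep rather than by adjacent-pair differences.

## The synthetic-data generator

`generate_dataset()` emulates the $n \times J$ array of correlation
matrices the inference assumes: each edge's z value is baseline plus a
linear-in-condition planted effect plus independent Gaussian noise,
back-transformed to correlations (automatically inside $(-1, 1)$).
`default_ground_truth()` supplies a block-structured baseline (4 communities,
within-block $r = 0.5$, between $0.1$) so density and modularity metrics are
non-trivial on fixtures, with 8 disjoint planted edges declining by
$3\sigma$ in total and 5 nodes gaining signal — the canonical recovery
regime used in validation (with $n = 20$ subjects, $J = 4$ conditions,
z-scale noise sd 0.1). Node signals are generated analogously on the raw
scale.

What the generator deliberately does *not* emulate: spatial correlation
between edges (real connectivity matrices have strongly dependent edges —
the independence here matches the Benjamini–Hochberg PRDS calibration
regime, and FDR control on real data rests on BH's robustness under
positive dependence, not on these simulations); temporal autocorrelation and
hemodynamics (correlations are generated directly, not from time series);
sampling variability of correlation estimates (noise is Gaussian on the z
scale with a fixed sd rather than the $1/\sqrt{T-3}$ sd of an estimated
correlation). Passing recovery and calibration tests therefore validates
the inferential machinery under its stated assumptions, not its behavior on
real fMRI data.

## Validation problem sizes

The shipped validation suite checks distances and efficiencies against a
Floyd–Warshall brute force (100 random graphs up to 30 vertices), modularity
against an exhaustive search over all partitions (graphs up to 8 vertices,
Bell$(8) = 4140$ partitions), the ANOVA against first-principles sums of
squares and `aov`, monotone invariance bit-for-bit on a 20-node matrix, the
degeneracy identity on 100 low-spread matrices, the modularity confound on
112-vertex ensembles with 100 replicates per cell, and FDR calibration /
$3\sigma$ recovery on 200 null replicates and 50 seeded effect datasets.
These sizes were chosen so the whole suite runs in well under a minute while
keeping Monte-Carlo standard errors small relative to the asserted margins.

## Limitations

* Inference assumes balanced complete designs; unbalanced or missing data
  require a genuine mixed-model fitter (an external fit can be plugged in at
  the `edge_linear_model()` surface).
* The sign assignment of differential SPNs is only meaningful for monotone
  experimental gradients; the package warns, but cannot repair, mixed-sign
  profiles.
* Local efficiency, clustering, betweenness and signed/weighted modularity
  are out of scope.
* The degeneracy check `direct_path_condition_holds()` verifies the
  sufficient "every edge is its own shortest path" condition directly;
  coarser spread-based sufficient conditions (like $w_{max} \le 2 w_{min}$)
  imply it but are not required.

## A worked example

```{r example}
sim <- generate_dataset(20, 4, truth = default_ground_truth(30), seed = 1)
res <- differential_spn(sim$data, alpha0 = 0.05)
res
inc <- included_edges(res)
head(inc$minus[, c("node_i", "node_j", "statistic", "q_value", "sign")])

W <- weight_matrix(sim$data$r[, , 1, 1])
c(
  weighted_density = weighted_density(W),
  integrated_efficiency = density_integrated_metric(W, mode = "absolute")
)
```
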