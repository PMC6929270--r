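---
title: "Measuring clustering robustness across parameter settings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring clustering robustness across parameter settings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(robustclust)
```

## The metric

`robustclust` measures how stable a clustering algorithm's output is as one
of its settings varies. Given `r` runs of one algorithm on one dataset —
each run a flat, non-overlapping clustering produced with a different value
of the swept setting — every unordered pair of items that shares a cluster
in at least one run receives a score: the fraction of runs in which it is
co-clustered. Robustness is the mean of these scores, computed as

$$R = \frac{t}{d\,r},$$

with `t` the total number of co-clustered pairs summed over runs, `d` the
number of distinct ever-co-clustered pairs, and `r` the number of runs.

Assumptions worth making explicit:

* **Only co-clustered pairs enter.** Items that are never placed in any
  multi-item cluster (singletons, unclustered residue) contribute nothing;
  `R` is conditioned on "the pair was put together at least once". A
  degenerate collection in which *no* pair is ever co-clustered has no
  defined robustness, and `robustness()` raises a distinct
  "undefined robustness" error rather than returning 0 or `NaN`, because by
  construction `R` lies in `(0, 1]`.
* **Runs need not cover the same items.** The universe is the union of
  items over runs; paraclique, NNN and QT legitimately leave residue.
  Co-clustering is a boolean per run — a pair inside two clusters of one
  run cannot exist (clusters are disjoint), and a pair spanning NNN's
  single shared element is counted at most once per run.
* **Robustness is not quality.** A constant algorithm that always emits the
  same partition has `R = 1` regardless of whether the partition means
  anything. The metric answers "how much does the output move as settings
  move", nothing more; it deliberately makes no reference to ground truth.

`R` is stored as its exact integer decomposition (`t`, `d`, `r`) and
rendered to 3 decimal places (per-pair scores to 4), the conventional
reporting precision; full precision is always available from the integers.

Cross-dataset summaries report the mean of per-dataset `R` values and their
coefficient of variation CV = sd/mean. The **sample** standard deviation
(n − 1 denominator) is used; with a single dataset the CV is reported as
absent (`NA`), not zero.

## Clustering algorithms and their swept settings

The package implements natively the methods whose sweeps it measures;
externally produced clusterings (e.g. WGCNA modules or CLICK solutions) are
ingested as membership files instead, since reimplementing those pipelines
is out of scope.

**Distance conventions.** All correlation-driven methods share one
similarity structure: Pearson correlation between gene rows. Hierarchical
and QT clustering consume the dissimilarity `1 − r`; NNN consumes `r`
itself; paraclique consumes the graph thresholded at `τ`. The two
centroid-based methods (k-means, SOM) operate on Euclidean distances
between **row-standardized** genes (mean 0, sd 1), under which squared
distance is proportional to `1 − r` — so "similar" means the same thing
across all six methods: same expression *shape*, not same absolute level.
Raw-level clustering remains available (`scale_rows = FALSE`, or
`distance = "euclidean"` in sweep specs).

* **Hierarchical** (`average`/UPGMA, `complete`, `mcquitty`/WPGMA, `ward`):
  the tree is fit once per sweep and cut at each requested cluster count.
  Ward uses the squared-dissimilarity convention (`hclust`'s `ward.D2`).
  Because all runs cut the same tree, a pair merged at `k` clusters remains
  merged at every `k' < k`: each pair's co-clustering runs form a suffix of
  the run order (sweeps are ordered by decreasing cluster count), giving
  the closed form `R = Σ_P (r − first(P) + 1)/(d·r)`. The test suite
  asserts both the suffix property and the closed form on random
  dissimilarities; this nestedness is the structural explanation for
  hierarchical methods' high robustness.
* **k-means**: Lloyd's algorithm, `nstart = 10` restarts, deterministic
  given a seed. Clusters empty at convergence are dropped (the run then has
  fewer than `k` clusters); robustness consumes only the partition.
* **QT clustering**: greedy growth of a candidate cluster around every
  remaining seed item — always adding the item that minimizes the resulting
  diameter, under the hard cap — then emitting the largest candidate and
  repeating. All ties (growth ties, candidate-size ties) resolve by
  lexicographic item ID, so the algorithm is bit-reproducible. Tests verify
  round-by-round against exhaustive search that the emitted cluster always
  attains the maximum feasible size on 5-item instances, and that every
  cluster respects the diameter cap on every input.
* **SOM**: online training, `100·n` presentations in seeded random order,
  learning rate decaying linearly 0.05 → 0.01, Gaussian neighborhood with
  radius decaying from half the grid diagonal to 1, code vectors
  initialized from randomly drawn genes. Rectangular and hexagonal layouts
  differ only in node coordinates (hexagonal rows offset by half a unit).
  These schedule constants are fixed package conventions — the method's
  common descriptions leave them open — and are deliberately not exposed as
  sweep settings.
* **Paraclique**: enumerate the maximum cliques of the thresholded graph
  (deduplicated, ordered lexicographically so that "the i-th maximum
  clique" is well defined); seed from the chosen clique; accrete any
  outside vertex adjacent to at least `size − g` current members,
  lexicographically smallest first, rescanning until fixpoint; remove the
  paraclique and repeat from the residual graph's first maximum clique
  until its maximum clique drops below `min_clique_size`. The glom factor
  `g` defaults to 1 and is tested against the current paraclique size, not
  the seed size — the canonical accretion rule. `min_clique_size` defaults
  to 5, the customary floor for genome-scale graphs; the package's small
  fixtures pass 3 explicitly. A `max_paracliques` cap is available since
  the number of paracliques, unlike most settings here, has no natural
  endpoint.
* **NNN**: symmetrized k-nearest-neighbor graph (tie-break on equal
  similarity: ascending item ID), cliques of exactly `clique_size`
  (default 3) merged through shared vertices into preliminary networks,
  split at articulation points into biconnected components, then any
  cluster above half the item count is split further. Two conventions had
  to be fixed where common descriptions are silent: (a) an articulation
  vertex, which legitimately belongs to each component it joins, is
  assigned to the first of its clusters in deterministic order before pair
  counting, since the metric requires disjoint clusters — a pair containing
  it therefore counts at most once per run; (b) an oversized cluster with
  no articulation point is split by removing its minimum-degree vertex
  (ties by ID) and re-splitting, the removed vertex following its smallest
  neighbor's component when that shrinks the cluster and becoming a
  singleton otherwise. Both choices affect only boundary items.

## Co-expression graphs and threshold choice

`threshold_graph()` keeps an edge iff its Pearson weight is **at or above**
`τ` — a signed comparison, matching the convention that a co-expression
edge represents positive correlation; `absolute = TRUE` switches to
`|w| ≥ τ` for pipelines that treat strong negative correlation as
connectivity. Isolated vertices stay in the graph (they can never join a
paraclique of size ≥ 2, consistent with robustness ignoring
never-co-clustered items).

`suggest_threshold()` is an explicitly *advisory* heuristic: over an
ascending candidate grid it computes the unweighted adjacency's leading
eigenvalue, and returns the last candidate before that eigenvalue's
steepest relative decline — the highest threshold at which the network's
dominant connectivity is still intact. On module-structured data this lands
between the background and intra-module correlation levels. The exact
inflection criterion used by published spectral-thresholding work is not
reproduced here; every pipeline in the package accepts a user-supplied `τ`,
which is the supported way to use thresholds chosen by other means. The
per-candidate diagnostics table (edge count, leading eigenvalue, component
count) is returned so the curve can be inspected directly.

## The synthetic generator

`generate_expression()` draws module-structured data from a latent-factor
model: module `m` has one latent sample profile `L_m ~ N(0, 1)`; a member
gene is `baseline + λ·L_m + ε` with `ε ~ N(0, σ²)` and loading
`λ = σ·sqrt(ρ/(1−ρ))`, so the expected correlation between two genes of
the same module is exactly `ρ = λ²/(λ² + σ²)` for **any** noise scale σ.
This closed-form calibration is why the generator takes both a correlation
target and a noise sd: the first fixes the correlation structure, the
second only the absolute scale of variation. Background genes load
analogously on one weak global factor (independent when
`background_corr = 0`), and per-gene baselines are uniform on [6, 12] to
mimic log2 microarray intensities. Generation is O(genes × samples) and
fully deterministic given the seed; ground-truth labels are returned
alongside and written to a side TSV by the CLI, never consumed by any
algorithm.

Defaults (2 modules × 20 genes, 50 background genes, 40 samples, ρ = 0.9
inside modules vs 0.1 background, σ = 1) describe a cleanly separated
design on which clustering *should* succeed. The generator deliberately
does **not** emulate microarray platform artifacts, batch effects,
missingness, heavy-tailed noise, overlapping or nested modules, or
correlated background structure. Consequently, passing tests on synthetic
data show that the algorithms and the metric behave as specified under
their own assumptions — not that any algorithm will recover biology from a
real compendium, where robustness values are typically lower and the
ordering between middling algorithms can differ.

## Scope of the bundled experiments

The package's tests exercise the full pipeline at desk scale: 30-item
dissimilarities for the hierarchical suffix law, 45–90-gene synthetic
matrices for the sweeps, 200 random instances against the brute-force
pair-counting oracle, 100 random graphs (≤ 12 vertices) against exhaustive
clique enumeration, and 5-seed replicates for the directional comparison
of hierarchical versus k-means robustness. At these sizes hierarchical
sweeps dominate k-means sweeps in mean robustness — the tree-cut mechanism
at work — and paraclique sweeps over the starting clique on a fixture
whose maximum cliques overlap heavily (K8 minus a perfect matching) give
`R = 1` exactly. Published full-scale comparisons on two dozen GEO
compendia report absolute levels (hierarchical and paraclique above 0.87,
others below 0.5) that depend on those specific datasets and are not
targets of this package's test suite; the directional and structural
properties are.

Default sweep ranges follow the same practice: cluster counts 200–300
(step 10, r = 11; a `scale` factor shrinks the range for small matrices),
QT diameters 0.05–0.5 step 0.05, NNN neighborhood sizes 16–25, five SOM
grid sizes × two topologies derived from the cluster-count range, and one
paraclique run per starting maximum clique. Mean cluster size per run is
reported (`run_diagnostics()`) as the diagnostic for judging whether two
algorithms' sweeps produced clusters of comparable scale; it is advisory,
not enforced, because no principled enforcement rule exists.

## Numerical and formatting conventions

* Items are compared by exact string identity; all tie-breaks
  (QT growth and winner selection, clique ordering, k-NN ties, nearest
  centroid ties via `which.min`) resolve lexicographically or by first
  index, so every nominally deterministic algorithm is bit-reproducible,
  and the stochastic ones (k-means, SOM) are bit-reproducible given a seed.
* Pair counting aggregates per-run pair keys (memory scales with `d`, the
  number of observed pairs, not with `n²`).
* Correlations are clamped to [−1, 1] to absorb floating-point spill;
  constant genes are rejected by `correlation_matrix()` and flagged by
  `read_expression()`.
* Membership files are two-column TSV (`cluster_id<TAB>item_id`), UTF-8,
  `#` comments ignored; item IDs containing tabs or newlines are rejected
  at write time rather than silently corrupted. Cluster IDs are scoped to
  one file — the metric never needs cluster identity across runs.
* Genes with missing values are dropped on load (with a message), not
  imputed.

## Known limitations

* Overlapping clusterings are out of scope; NNN's single shared element is
  resolved by assignment, as described above.
* The spectral threshold suggestion is a labeled heuristic, not a
  reimplementation of any published criterion.
* `robustness_report()` runs cells sequentially; there is no scheduling,
  and the QT implementation, though polynomial, is the slowest component
  on large inputs (its published behavior includes practical
  non-termination on big matrices — failed cells are reported as missing,
  not fatal).
* No combined accuracy-plus-robustness score is offered; the two notions
  are intentionally kept apart.
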