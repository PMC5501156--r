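---
title: "From expression matrices to a queryable gene graph: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From expression matrices to a queryable gene graph: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`exprgraph` chains a classical single-factor microarray analysis into a
typed property graph. This vignette explains each method, the assumptions
behind it, the tunable parameters, and the design decisions taken where
several defensible choices existed. It states no empirical result that the
package's tests and acceptance script do not themselves compute.

## Normalization and summarization

Raw probe intensities are assumed positive and approximately log-normal.
The normalization path is RMA-style: quantile normalization on the linear
scale, log2, then probe-set summarization by Tukey's median polish.

* **Quantile normalization** maps every sample's empirical distribution to
  the across-sample mean of order statistics. Ties are broken by row
  order, a deterministic rule chosen so that two properties hold exactly:
  all normalized columns share an identical sorted value vector, and the
  operation is idempotent. (Tie-averaging variants trade these exact
  properties for symmetric tie handling; continuous microarray
  intensities make ties a non-issue in practice.) The implementation is
  cross-checked in the tests against `limma::normalizeQuantiles` on
  tie-free data.
* **Median polish** fits the additive model
  `log2 x[i,j] = overall + probe_i + sample_j + residual` robustly, with
  rows-first sweeps, at most 10 iterations, stopping when the reduction in
  the sum of absolute residuals falls below 1% of the current total (the
  classical defaults). The per-sample summary is `overall + sample_j`. A
  probe set with a single probe passes through unchanged. The convolution
  background-correction step of full RMA is omitted: the model behind it
  targets optical background that the synthetic data (and any
  pre-background-corrected matrix) does not carry.
* **MAS5 is not supported.** Its Tukey-biweight/scaling machinery is a
  different estimator family and is deliberately out of scope; the
  configuration validator refuses it explicitly rather than silently
  substituting.

The method is recorded in a `method_tag` attribute and in provenance, so a
result never silently claims to be something else.

## Expression set and annotation

Sample metadata arrives as a phenodata table with the two required columns
`SETS` (group label) and `SAMPLE_NAME`; extra columns are preserved. The
container is a `SummarizedExperiment` — the standard Bioconductor binding
of an assay matrix to sample metadata — with matrix columns reordered to
phenodata row order at construction.

Probe sets map to genes via an annotation table keyed by `probeset_id`.
When several probe sets map to one gene, the one with the **highest mean
expression across samples** is retained (ties broken by lexicographic
probe-set id). This rule is deterministic, common practice, and — unlike
averaging — never fabricates expression values: annotation only selects
rows. The pipeline runs differential expression at probe-set level first
and then lets each gene inherit the statistics of its retained probe set,
preserving the workflow order normalization → e-set → DE → annotation →
clusterization → functional analysis.

## Differential expression

Inference is the standard empirical-Bayes moderated t on group-means
parameterization, assuming within-group normality and a shared per-gene
variance across groups:

* pooled residual variance `s²_g` with `d = n − #groups` degrees of
  freedom;
* a scaled inverse chi-square prior `(d₀, s₀²)` estimated by matching the
  mean and variance of `log s²_g` to the theoretical scaled-F
  distribution. The trigamma inversion uses Newton iteration with the
  asymptotic start `x ≈ 0.5 + 1/y`, converging to relative steps below
  1e-10. If the moment estimate of the dispersion is non-positive (data
  compatible with all-equal true variances), the prior degrees of freedom
  are set to infinity and every posterior variance collapses to `s₀²`,
  with an explicit flag; with fewer than 10 usable genes the function
  falls back to the ordinary t (d₀ = 0), also flagged;
* posterior variance `s̃²_g = (d₀ s₀² + d s²_g)/(d₀ + d)`; moderated
  `t = log2FC / sqrt(s̃²_g (1/n_a + 1/n_b))` with `d + d₀` degrees of
  freedom. Setting `d₀ = 0` reproduces the ordinary pooled-variance t
  exactly, which the tests assert against `t.test`.

The tests also cross-check `d₀`, `s₀²`, t and p against `limma`'s
`lmFit`/`eBayes` on the same data (agreement to ~1e-10); limma remains a
test-only dependency so that the package's inferential core is
self-contained and fully inspectable.

Multiple testing uses Benjamini–Hochberg step-up adjustment **within each
pairwise contrast** (a global family is available by argument). Selection
uses strict inequalities — FDR < 0.05 and |log2FC| > 1 by default — and in
multi-group designs the experiment's DE set is the union of per-contrast
selections, with per-gene provenance of the selecting contrasts.

## Clustering

Clustering operates on the DE-selected gene submatrix, using the Pearson
dissimilarity `d = 1 − r` between gene profiles (range [0, 2]; genes with
zero variance are refused by name). Two methods are provided:

* **hierarchical**, average linkage by default, via `hclust`/`cutree`
  (merge ties resolved by `hclust`'s own deterministic rule);
* **PAM k-medoids**, implemented natively: BUILD seeds medoids greedily,
  SWAP repeatedly applies the best strictly-improving medoid/non-medoid
  exchange until a local optimum, ties broken by index order. The
  objective (total dissimilarity to nearest medoid) is reported.

PAM is a local search. On tiny random instances (n ≤ 8) it usually—but
not always—attains the enumerated global optimum; the reference
`cluster::pam` exhibits the same behavior on the same instances (the two
agree on the vast majority and neither dominates). The tests therefore
assert the true algorithmic contracts (monotone objective, swap-local
optimality, nearest-medoid assignment, determinism) rather than global
optimality, and the package makes no optimality claim beyond local
convergence.

When `k` is not given it is chosen by maximizing the average silhouette
width over k ∈ {2, …, 10} on the same dissimilarity (smallest k on ties) —
deterministic and standard. Clusters receive display names
`"<method>:<k>:<index>@<experiment>"` (`clustInfo`), parseable and unique
per experiment, which later key the graph's CLUSTER nodes.

## Over-representation analysis

Each cluster is tested against a caller-supplied term-to-gene mapping
(GMT) with the hypergeometric upper tail, computed by `phyper` (log-space
stable) and verified in the tests against an independent
log-combinatorics summation to below 1e-12. The **universe** is the set
of genes on the platform; for collections of experiments on different
platforms it is the intersection of the deduplicated platform sets (the
harmonized gene space). Query genes and term members are intersected with
the universe before counting, so foreign identifiers can never inflate
counts. Significance is a raw p < 0.001 cut by default — a deliberately
restrictive threshold in lieu of multiple-testing correction, which is
available by argument but off by default. Terms are flat gene sets; no
ontology-graph conditioning is attempted.

## The property graph

Node labels: `GENE`, `BP`, `CLUSTER`, `EXPERIMENT`, `ORGANISM`, `HUB`.
Edge types with endpoint constraints: `PPI_INTERACTION` (GENE–GENE,
undirected, stored once with canonical endpoint ordering),
`WAS_SELECTED` (EXPERIMENT→GENE, carrying log2FC/FDR/direction),
`WAS_CLUSTERIZED` (GENE→CLUSTER), `WAS_REPRESENTED` (CLUSTER→BP),
`AS_HUBS` (GENE→HUB), `BELONGS_TO` (GENE→ORGANISM). Constraints are
enforced on insertion with typed errors; duplicate `(source, target,
type)` edges are impossible by construction, and node removal cascades to
incident edges, so referential integrity holds after any operation
sequence. PPI edges carry the seven STRING-style evidence channels plus a
`combined_score` normalized to [0, 1] (so the conventional 0.80 cut is
scale-unambiguous).

Re-loading an experiment of the same name **replaces** its subgraph
(experiment node, its clusters and their edges) rather than appending —
idempotency is the property that makes repeated pipeline runs safe. BP
nodes are shared vocabulary and persist. Selected genes missing from the
background are auto-created with minimal properties and reported, rather
than silently dropped.

Persistence: GraphML with typed keys and JSON (both lossless round-trips,
numerics serialized at full precision), plus a write-only Cypher script of
`CREATE` statements (one per node and per relationship) for loading into
a Cypher-compatible store.

### Queries

* `schema_summary`: the realized (label, type, label) triples.
* `degree`: adjacent-edge count per node for one edge type; for
  undirected types the degrees sum to twice the edge count.
* `hub_candidates`: for every DE gene, the number of *distinct* PPI
  partners with combined score strictly above the threshold (default
  0.80) that are themselves clusterized into a BP-represented cluster —
  the full path pattern, not bare PPI degree. Ordered by score
  descending, ties by symbol ascending (an explicit rule because a top-N
  cut makes ties consequential); partner symbols and the partners'
  cluster BP terms are collected per gene, not pooled.
* `create_hub`: one HUB node plus `AS_HUBS` edges from genes with score
  strictly above the threshold (default 50); re-running replaces.
* `coexpressed_with`: partners sharing clusters with the query gene,
  scored by the number of distinct shared clusters across all loaded
  experiments.

All four are verified against naive nested-loop pattern matchers on
randomized schema-valid graphs.

## Meta-analysis

Experiments are integrated at the results level, not the matrix level:
each study is normalized and tested separately (no cross-study batch
correction is attempted), gene spaces are harmonized to their
intersection, the enrichment universe becomes that intersection, and each
experiment contributes its own EXPERIMENT/CLUSTER nodes to a graph with
shared GENE nodes. Consequently per-experiment inference is provably
unchanged by the collection, and integration order cannot affect the
final graph.

## Provenance

Every pipeline run records a bipartite, acyclic data-derivation graph:
one operation node per analysis stage (normalization, e-set, differential
expression, annotation, clusterization, functional analysis, graph
load) with parameters recorded verbatim — including defaults the user
never set — and data nodes keyed by SHA-256 content hashes, so identical
inputs and seeds reproduce identical hashes across runs. Stage-level
granularity was chosen over function-level: it matches how the workflow
is parameterized and keeps the derivation graph readable. Acyclicity and
the single-generator invariant are verified on export.

## The synthetic-data generator

The generator emulates a single-factor Affymetrix-style study: per-gene
log2 baselines ~ N(8, 1.5²), additive probe affinities ~ N(0, 0.4²), a
±`de_log2fc` effect for the designated DE genes in the second group
(signs randomized), i.i.d. N(0, `noise_sd`²) noise per probe and sample,
exponentiated to strictly positive intensities. PPI edges are
Erdős–Rényi with evidence channels uniform on [0, 1] and combined scores
uniform on [0.5, 1], so the 0.80 threshold splits edges non-trivially.
Term sets are uniform draws except designated enriched terms that take
80% of their members from the DE genes. All outputs are deterministic
given the spec's seed (one sub-seeded stream per generator call).

It does **not** emulate batch effects, probe-sequence biases, spatial
artifacts, correlated gene modules beyond the group effect, or the
degree heterogeneity of real PPI networks. Passing tests therefore
demonstrate correctness of the algorithms under the stated model, not
robustness to those real-data phenomena.

### Study conditions used by tests and the acceptance script

* Recovery simulation: 2,000 genes × 4 probes, 10 vs 10 samples, 100 DE
  genes at log2FC = 2, noise sd 0.5 — sensitivity and empirical FDR are
  measured at the default thresholds. Null simulation: 1,000 genes × 2
  probes, no planted effects.
* Hyperparameter recovery: 5,000 simulated variances from a known
  (d₀, s₀²) prior at 18 residual df.
* End-to-end fixture: 300 genes × 3 probes, 5 vs 5 samples, 40 DE genes,
  30 terms × 15 genes, PPI edge probability 0.15. At this desk scale PPI
  degrees are small, so the fixture's hub step uses a score threshold of
  0 (strictly positive scores qualify); the function defaults keep the
  conventional cut of 50, which is meaningful on genome-scale networks.

## Known limitations

* Single-factor designs only: no paired samples, covariates, or
  interaction terms.
* Probe-level input must already be a text matrix; vendor binary formats
  are out of scope.
* One probe set maps to at most one gene; multi-mapping is not modeled.
* The graph store is in-process and single-writer; it targets analysis
  provenance and interchange, not concurrent serving.
* PAM's local optimum is not guaranteed global (see Clustering).
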