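---
title: "Recursive ensemble clustering with explicit robustness values"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recursive ensemble clustering with explicit robustness values}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Motivation

Clustering is the first step of most scRNA-seq analyses, and its result
depends heavily on the method used: different algorithms rest on different
hypotheses, and their performance varies with properties of the data (size
and separation of the populations) that are unknown beforehand. Ensemble
algorithms mitigate this by combining several base clusterings, but most of
them do so by *minimizing* the differences between the base results, and
return a single flat consensus without any measure of confidence.

`scEnsembleTree` takes the opposite view: the differences between base
clusterings are informative. Cells that every method groups together form a
*robust cluster* whose degree of inter-method agreement can be quantified;
cells the methods disagree on are set aside in a *leftover cluster* rather
than forced into a consensus. Applying this recursively produces a cluster
tree at multiple resolutions, where every split carries an explicit
robustness value in $[0, 1]$ and an explicit set of unassigned cells.

## The consensus model

Let a pool of $n$ cells be clustered independently by $M$ methods, giving a
set of *base clusters*. For two base clusters $x$ and $y$ from different
methods, the similarity is the minimal proportion of shared cells,

$$S_{x,y} = \min\!\left(\frac{N_{x\cap y}}{N_x},\; \frac{N_{x\cap y}}{N_y}\right),$$

where $N_x$ is the size of $x$ and $N_{x\cap y}$ the size of the
intersection. $S_{x,y} = 1$ iff the clusters are identical and $0$ iff they
are disjoint. This is the smaller of the two association-rule confidences
$\mathrm{conf}(x \to y)$ and $\mathrm{conf}(y \to x)$; we compute it by
direct set intersection, which is exact and removes any dependence on a
frequent-itemset mining library.

Base clusters become vertices of a graph whose edges are the similarities.
Edges with $S_{x,y} \le S_{\lim}$ are discarded (strictly: an edge at
exactly $S_{\lim}$ is weak). The default $S_{\lim} = 0.5$ reads as "the two
clusters share the majority of their cells". Each connected component $z$
of the filtered graph yields one candidate robust cluster: the cells
grouped together in *all* of its base clusters (the intersection of the
member cell sets), with robustness

$$R_z = \frac{\sum_{x,y} S_{x,y}}{M(M-1)/2},$$

the sum of the component's surviving edge weights over the edge sum of a
complete agreement among all $M$ methods. $R_z = 1$ iff every method
predicted exactly the same cluster; an isolated vertex has $R_z = 0$. The
numerator deliberately sums only the strong edges: weak edges are removed
before components exist, so the subgraph whose weighted density is measured
is the filtered one.

Components are accepted when $R_z$ strictly exceeds a threshold. The
baseline threshold is the robustness expected if a strict majority
$m = \lfloor M/2\rfloor + 1$ of methods agreed at exactly $S_{\lim}$:

$$R_{\lim} = \frac{S_{\lim}\, m(m-1)/2}{M(M-1)/2},$$

which is $0.25$ for the default $S_{\lim} = 0.5$ and $M = 4$. All cells not
claimed by an accepted component form the leftover cluster, whose
robustness is defined to be exactly $0$: its existence reflects a lack of
agreement, not a prediction.

Two corner cases need a deterministic rule. A component can, through
transitive strong edges, contain two clusters of the same method; their
intersection is then empty and the component is dropped (its cells fall to
the leftover) because "grouped together in all base clusters" is
unsatisfiable. And if two accepted cores ever overlap (possible only
through threshold edge cases), the overlap goes to the component with
higher robustness, ties broken by larger core and then by lexicographically
smallest member; the outputs therefore always partition the pool.

## The characterization filter

High inter-method agreement does not guarantee biological meaning: methods
can agree on an arbitrary split of a homogeneous population. Each robust
cluster must therefore be *well-characterized*: it must have at least 10
marker genes, defined as genes expressed more than 16-fold
($\log_2 \mathrm{FC} > 4$) above the rest of the pool. Fold changes are
ratios of pseudocount-shifted mean de-logged normalized expression, and a
two-sided Wilcoxon rank-sum test with Bonferroni correction over all genes
(adjusted $p < 0.05$) guards against spurious ratios in small clusters; the
test can be disabled for fold-change-only behaviour.

Robust clusters failing the rule are merged into the leftover and the
leftover's markers are recomputed (each robust cluster is tested against
the rest of the *pool*, so its own markers are unaffected by the merge). If
no robust cluster survives, no split is made at all — this is the main
guard against over-clustering. The leftover's own marker count never vetoes
a split: it is a residual, not a prediction. Whether the leftover should
also have to be well-characterized is genuinely ambiguous; we chose the
permissive reading and expose the marker thresholds in the configuration.

## Recursion and the rising threshold

Each accepted cluster (robust or leftover) with at least `min_cells` cells
(default 100, matching the smallest pool the smallest-scale base method is
comfortable with) is re-clustered from scratch: highly variable genes are
re-selected on the pool's own counts, the ensemble re-run, and the
consensus re-derived. A subcluster $i$ of a cluster $z$ is accepted only if
$R_i > \max(R_{\lim}, R_z)$: subdividing must *increase* the agreement
between methods. Leftover clusters recurse with $R_z = 0$, so their
children face exactly $R_{\lim}$. Effective thresholds are therefore
non-decreasing along every root-to-leaf path, which the test suite asserts
on every fitted tree.

Nodes are labelled from the root `C`: robust children `C.1, C.2, ...` in
decreasing size, the leftover child `C.L`, recursively (`C.L.1`,
`C.L.L`, ...). The fit returns four tables — `meta` (sizes, robustness,
parenthood), `samples` (each cell's label at every resolution), `features`
(markers per cluster) and `methods` (which base methods contributed to each
cluster) — which `write_result_tables()` serializes to CSV bit-exactly.

## The base clusterer roster

The consensus layer is method-agnostic: any function mapping a normalized
matrix and a seed to a partition can join the roster via `new_clusterer()`,
and externally computed partitions can be injected with
`import_partitions()`. The four built-ins cover distinct methodological
families in common use:

* `knn_louvain` — community detection by modularity optimization on a
  k-nearest-neighbour graph of a 50-component PCA embedding of
  log-normalized expression;
* `snn_louvain` — the same optimization on a shared-nearest-neighbour graph
  with Jaccard edge weights, the construction popularized by the main
  single-cell toolkits;
* `density_scan` — a DBSCAN-style density scan (core points by
  neighbourhood count at an automatically chosen radius, clusters as
  $\epsilon$-connected components, remaining cells attached to the nearest
  core point so the result is a partition) on a 10-dimensional embedding of
  log2-CPM expression;
* `hier_silhouette` — Ward hierarchical clustering of the embedding with
  the cut chosen by maximal average silhouette width over $k = 2\ldots 8$.

Per-method seeds are derived as `seed + hash(method name)` (and per-pool
runs additionally fold in the pool label), so methods are decoupled but the
whole fit is reproducible. A clusterer that errors is dropped with a
warning and $M$ becomes the number of partitions actually produced, keeping
$R_z$ on a scale relative to achievable agreement; fewer than two surviving
partitions makes the pool a leaf.

On data where the original large ecosystem tools are available, their
partitions can be injected through `import_partitions()`; the built-ins are
self-contained analogues, not re-implementations, and their default
parameters (50 PCA components, $k$-neighbours $= \min(15, n/5)$) follow
common practice rather than any specific tool.

## Preprocessing choices

Counts are log-normalized as $\log(1 + 10^4\, c_{gc}/t_c)$ with $t_c$ the
cell total; the density clusterer instead receives
$\log_2(1 + 10^6\, c_{gc}/t_c)$ (log2-CPM — on UMI data without gene
lengths, CPM and TPM coincide). Highly variable genes (default
`k_hvg = 1000`) are ranked by the variance of log-normalized expression
standardized against a loess mean–variance trend, falling back to raw
variance when fewer than 20 distinct mean bins make the trend unreliable.
Ties are broken by gene id, making selection stable under gene reordering.
Zero-total cells produce all-zero columns with a warning. The pseudocount
inside every log is 1.

## The synthetic generator

`simulate_cells()` provides ground-truth-labelled datasets along four
design axes: number of clusters, balanced versus geometric-imbalanced
sizes, and related versus unrelated transcriptomes. Under the imbalanced
scheme cluster $i$ of $k$ receives $\lfloor N\,2^{-i}/(1 - 2^{-k})\rfloor$
cells — normalized geometric weights, floored, with no redistribution of
the shortfall, so $N = 10000, k = 5$ gives exactly
$\{5161, 2580, 1290, 645, 322\}$ cells (9998 in total). Unrelated designs
perturb a common base profile independently per cluster; related designs
perturb it along a chain (cluster $i+1$ derives from cluster $i$), giving
transcriptome correlations that decay with chain distance, as with
developmentally related cell types.

Counts are gamma–Poisson (negative binomial, $\mathrm{var} = \mu +
\phi\mu^2$) around profile-by-library-size expectations with log-normal
library sizes. This reproduces the first- and second-moment structure of
UMI data; it does not model batch effects, doublets, ambient RNA, zero
inflation beyond NB, or trajectory-like continua. Default parameters —
2000 genes, 10% of genes perturbed per cluster at a mean log2 fold factor
of 6 (sd 0.5, random sign), dispersion 0.15, library-size log-sd 0.25
around 5000 counts — describe strongly separated populations of the kind a
competent pipeline must recover perfectly; tests passing on these data
therefore demonstrate correctness of the machinery, not performance on
subtle real-data structure.

## Numerical and testing choices

Strict inequalities are used at both thresholds ($S > S_{\lim}$,
$R > R_{\lim}$). Result tables serialize doubles with 17 significant
digits so reloads are bit-exact. The rank-sum p-value uses the normal
approximation with tie and continuity corrections (equivalent to
`wilcox.test(exact = FALSE)`), computed only for fold-change candidates
with the Bonferroni multiplier still equal to the total number of genes.
NMI uses max-entropy normalization by default (min/sqrt/sum variants are
available) and is undefined when both partitions are single-cluster, as is
the silhouette for a single cluster; neighbourhood purity is a kNN label
vote (default 50 neighbours) in the same expression space as the
silhouette — the feature space for both intrinsic metrics is a
configuration choice, not a fidelity claim.

The test suite validates the consensus layer against brute-force oracles
(pair-counting similarities, depth-first-search components, all-pairs
adjusted Rand) on hundreds of random partition sets, and runs the full
pipeline at deliberately moderate problem sizes — up to 2000 cells and
2000 genes for the five-population recovery runs and 1000 cells for the
single-population over-clustering runs, ten seeds each — chosen so the
whole suite completes in a few minutes on one core while still exercising
every recursion path.

## Known limitations

* The built-in clusterers are analogues of the common methodological
  families, not faithful ports of any published tool; exact base
  clusterings should be injected when fidelity to a specific tool matters.
* Robustness quantifies inter-method agreement, not correctness: methods
  sharing biases can agree robustly on the same artifact. The
  characterization filter catches only the transcriptionally invisible
  cases.
* All-pairs distance computations bound the practical pool size to a few
  tens of thousands of cells on one core.
* The marker rule (10 genes at 16-fold) is calibrated for well-separated
  cell types; closely related subtypes with graded expression differences
  will often be left unsplit, by design.
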