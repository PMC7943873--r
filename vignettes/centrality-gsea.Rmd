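---
title: "Centrality-based GSEA: model, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Centrality-based GSEA: model, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem

Pathway enrichment methods rank genes by a quantitative metric — usually an
expression change — and ask whether a gene set is concentrated at the
extremes of that ranking. When the starting material is a *list* of altered
genes (aCGH / exome findings, literature-mined protein lists), no such
metric exists. netgsea substitutes a topological one: each gene's
betweenness centrality in the protein–protein interaction network assembled
around the gene list. The premise is that genes mediating many shortest
paths between other genes in the disease network are the functionally
load-bearing ones, even when the signature genes themselves sit at the
periphery.

The package covers the full procedure: network construction from
interaction tables, centrality computation, a sigmoid transformation that
concentrates weight on hubs, pre-ranked GSEA with a permutation null, a
score-resampling specificity control, and threshold-based
over-representation analysis for comparison.

## Network construction

Interactions are read from MITAB 2.5 (PSICQUIC export style), SIF or plain
edge lists. Gene symbols are upper-cased throughout so that inconsistently
cased sources merge; in MITAB the symbol is taken from a
`uniprotkb:NAME(gene name)` alias token (columns 5–6) with fallback to the
primary identifier — providers vary, and no single column is universally
populated. Records can be filtered to a single NCBI taxon (default 9606) to
remove homology-inferred interactions; records with *unknown* taxon are
dropped by default and kept with `keep_unknown = TRUE`, the appropriate
mode for edge-list input that carries no taxon at all.

`expand_seeds()` grows the network from the signature: order 1 keeps
interactions touching a seed, order 2 additionally keeps interactions
touching any first interactor, emulating a second database query with the
first-interactor list. Interactions joining two nodes that are neither
seeds nor first interactors are excluded unless `include_outer_edges =
TRUE`; whether such edges belong in a second-order network is genuinely
ambiguous, so the choice is exposed rather than hard-coded. Self-loops and
duplicate edges are removed, and seeds absent from the interaction table
remain as isolated nodes — signature genes with zero centrality are still
part of the model and of the ranked list.

`prune_network()` removes isolated (degree 0) and terminal (degree 1)
nodes, *except seeds*. Pruning is a single simultaneous pass with degrees
measured on the input network: this is order-independent and reproducible,
and it does not shell arbitrarily deep into the network the way fixpoint
iteration would (a path's interior node that becomes isolated by the
removal of its ends is kept). `iterate = TRUE` gives the fixpoint variant
for sensitivity analysis.

## Betweenness and the Hill transformation

For node $n_i$ in a network of $N$ nodes,

$$C_B(n_i) \;=\; \sum_{j<k} \frac{\sigma_{jk}(n_i)}{\sigma_{jk}}
\cdot \frac{1}{\binom{N}{2}},$$

where $\sigma_{jk}$ counts geodesics between $n_j$ and $n_k$ and
$\sigma_{jk}(n_i)$ those passing through $n_i$ as an interior vertex. Pairs
in different components contribute nothing (their geodesic is undefined),
and $N$ is always the whole network's node count, even when the network is
disconnected. This `pairs` normalization is the package default; the
`standard` mode divides by $(N-1)(N-2)/2$ instead — the convention of
Cytoscape's NetworkAnalyzer — and relates to `pairs` by the exact factor
$N/(N-2)$. Closeness, computed for comparison only, is
$(c-1)/\sum_j d(i,j)$ within a component of size $c$.

Raw betweenness spans orders of magnitude and is useless as a GSEA weight
as-is: a handful of hubs would carry everything and the long tail nothing.
The Hill sigmoid

$$C'_B = \frac{C_B^{\,h}}{k + C_B^{\,h}}$$

compresses the tail toward 0 and saturates hubs toward 1. The denominator
is used exactly as written: $k$ is *not* raised to $h$ and therefore has
the units of $C_B^h$ (the conventional pharmacology form $k^h + C_B^h$ is
available behind `conventional = TRUE`). The value with $C_B^h = k$ scores
exactly 0.5.

Neither $h$ nor $k$ has a canonical value, so the package derives $k$ from
the data: `choose_k(values, h, q)` sets $k = Q_q^h$, with $Q_q$ the
$q$-quantile of the positive centralities, so the sigmoid's midpoint sits
at quantile $q$. The defaults $h = 4$, $q = 0.90$ aim the shoulder at the
top decile and produce a sharply saturated score in which roughly the most
central tenth of the network carries nearly all the weight — about 10–14%
of nodes score above 0.2 on the scale-free fixtures, reproducing the
published shape of the transform on real interaction networks. Both
parameters are exposed everywhere (`rank --h 4 --k auto:0.9`).

## Pre-ranked GSEA

The ranked list is all network genes by descending $C'_B$, ties broken by
ascending symbol so the ordering is fully deterministic; zero-centrality
genes stay in the list with score 0 and take part in the miss penalty.
Walking the list, the running sum rises by $|s|^p / \sum_{hits} |s|^p$ at a
member of the tested set and falls by $1/(n - n_{hits})$ otherwise; the
enrichment score (ES) is the maximum absolute deviation from zero, signed.
The default weighting exponent is $p = 1$, the standard weighted statistic.

With a single metric vector and no sample classes, the only available null
is gene-label permutation: for each permutation the ES is recomputed on the
same ranked scores with a random same-size membership. The permutation
p-value uses the add-one correction
$p = (1 + x) / (1 + n_{\text{same sign}})$, counting permutations of the
observed sign whose $|ES|$ reaches the observed one, so $p$ is never 0.
NES divides the observed ES by the mean $|ES|$ of same-sign permutations;
FDR is Benjamini–Hochberg across tested sets (the convention of the
pre-ranked R implementations, simpler and well-defined at small permutation
counts). For tiny universes `exhaustive = TRUE` enumerates every
membership, making the p-value exact.

The **resampling control** reruns the identical analysis after randomly
re-assigning the observed scores to gene identifiers (the score multiset is
bitwise unchanged). A pathway significant in both runs is flagged
`nonspecific`: its enrichment does not depend on *which* genes are central,
so it carries no topological information and should be discounted.

**ORA** is the classical comparison: genes with $C'_B$ strictly above a
threshold (0.2 / 0.5 / 0.8 by default, plus the whole network) are tested
per set with the upper-tail hypergeometric probability, BH-adjusted.
`method_grid()` assembles the pathway-by-method significance grid. The
reference set for published ORA is "human genome, protein coding"; offline,
the package uses the union of the gene-set collection and the network as
the universe so that the whole-network column is non-degenerate. Supplying
your own universe list overrides this.

## The synthetic fixture generator

Every stage is testable without database access through `synthetic_spec()`
/ `generate_network()` / `plant_sets()` / `emit_fixtures()`. The generator
emulates the statistical shape of seed-expanded interaction networks:

* **Preferential attachment** (from `attach_m` isolated founder nodes, each
  new node attaching to `attach_m` distinct nodes with probability
  proportional to degree + 1) — giving exactly `attach_m * (n - attach_m)`
  edges and the heavy-tailed betweenness distribution, spanning orders of
  magnitude, that motivates the Hill transform. An Erdős–Rényi graph would
  not reproduce that.
* **Peripheral seeds** — seed designation is sampled with probability
  proportional to $1/(\text{degree}+1)^2$, because real signature genes are
  mostly low-centrality while the hubs are first interactors.
* **A planted pathway** — one set sampled with probability proportional to
  $\exp(\text{hub\_bias} \cdot r)$, $r$ the normalized centrality rank,
  among uniform decoys. The defaults (500 nodes, `attach_m` 2, 15 seeds, 21
  sets of 30, `hub_bias` 8) are the package's standard study conditions: a
  signature the size of a typical patient gene list and a collection the
  size of a focused pathway screen.

What the generator does **not** emulate: Reactome's set-size distribution
and hierarchical redundancy, annotation bias (well-studied genes are both
more annotated and more connected), direct/physical edge semantics, and
literature-driven degree correlations. Passing tests therefore demonstrate
the statistical machinery, not performance on any real database snapshot.

## Numerical choices

* Ranking and top-$k$ ties break by ascending gene symbol; fractional
  top-$k$ uses `ceiling(fraction * N)` — deterministic, with the ±1
  ambiguity made visible rather than hidden.
* When the positive and negative running-sum extrema tie in magnitude
  (possible with $p = 0$), the ES resolves to the positive side; the
  comparison uses a $10^{-12}$ tolerance so that summation order cannot
  flip the sign.
* If every hit in a set has score 0 under $p > 0$, hit increments fall back
  to equal weights $1/n_{hits}$ — the weighted statistic is undefined
  there, and the set is typically a pure-tail set whose negative ES is
  still meaningful.
* Networks with fewer than 3 nodes have no interior pairs; all betweenness
  values are 0 rather than an error.
* Threshold selection is strict (`score > t`), so `t = 0` excludes the
  zero-score tail.
* All randomness flows through explicit named seeds (`gsea_seed`,
  `resample_seed`, generator `seed`); there is no hidden global state, and
  the pipeline manifest records every seed, so a config reproduces every
  output byte.

## Statistical behaviour and limitations

Two properties of the method at small problem sizes deserve emphasis; both
are measured by the package's own validation suite on the standard
synthetic conditions above.

**The weighted statistic saturates on sharply transformed metrics.** With
$h = 4$, $q = 0.90$ the score vector is nearly binary: ~50 genes near 1, the
rest near 0. Because hit increments are normalized within the hit set, a
random 30-gene set containing two or three high-scoring genes attains
almost the same ES as a set drawn almost entirely from the hubs — its
near-zero members barely dilute the statistic, and misses cost only
$1/(n - n_{hits})$ each. In the planted-set replicates the fully hub-biased
set reaches the top NES in well under half the runs with $p = 1$ (an
independent pre-ranked GSEA implementation, fgsea, returns the same ES and
p-value on the same fixtures, so this is a property of the statistic, not
of the code). The unweighted form ($p = 0$), which scores positional
concentration rather than score mass, recovers the planted set as top NES
essentially always in the same replicates. Users applying a sharp sigmoid
to a sparse centrality metric should consider `weight_p = 0`.

**The permutation floor bounds attainable FDR.** With $n_{perm}$
permutations the smallest possible p-value is $1/(n_{perm}+1)$; after BH
adjustment across $M$ sets, a set can only reach
$M/(n_{perm}+1)$. With 500 permutations and 21 sets that floor is 0.042 —
adjusted significance at 0.05 then requires beating *every* permutation.
For small collections, use $n_{perm}$ of several thousand, or read NES
ranks rather than adjusted p-values.

In the same replicates, the machinery around the statistic behaves as
designed: on resampled metrics with random sets the fraction of
$p < 0.05$ sits inside the exact binomial envelope around 0.05 (type-I
calibration); the resampling control never flags the planted set after
shuffling; and threshold-based ORA on the 0.5-score subset — which tests
membership concentration directly — detects the planted set essentially
always, mirroring the empirical observation that threshold ORA and GSEA
catch overlapping but distinct pathway lists.

## Validation problem sizes

The test suite validates betweenness against an explicit geodesic-counting
oracle on 200 random graphs of up to 12 nodes (both normalizations, to
1e−12), the enrichment score against a brute-force running-sum oracle on
1,000 random instances, Monte-Carlo against exhaustive permutation p-values
on a 6-gene universe, and the end-to-end pipeline for byte-identical
reproducibility on the 500-node standard fixture. Calibration and power
properties use 500-node networks with 500 permutations, 500 random sets
(type-I) and 50 planted-recovery replicates — sizes chosen so the whole
suite exercises study-scale behaviour while remaining a desk-scale
computation.

## Open choices made

* MITAB node identity: alias-column gene names preferred over primary
  accessions, because the method operates on gene-symbol networks.
* Second-order expansion excludes outer-ring edges by default (flag to
  include), as described above.
* The control comparison uses adjusted p-values at `alpha = 0.05` by
  default; the level is a parameter, since discounting rules vary between
  analyses.
* Gene ratio is reported both as set-size-in-network over network size
  (`gene_ratio`, the dot-plot convention for network GSEA) and as
  leading-edge over set size (`gene_ratio_le`).
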