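---
title: "Network-pharmacology core-target screening: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network-pharmacology core-target screening: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netpharm)
```

## The problem

Multi-compound herbal formulas act on many protein targets at once, so
their mechanism cannot be read off a single drug-target pair. Network
pharmacology infers a candidate mechanism by (i) collecting the predicted
and curated targets of the formula's blood-absorbed compounds, (ii)
collecting disease-associated targets from curated databases and from
differential expression in case/control cohorts, (iii) projecting both
sets onto a protein-protein interactome and intersecting the resulting
subnetworks, (iv) ranking the intersection by topological centrality to
nominate a *core target* set, and (v) interpreting the core set by
pathway over-representation. `netpharm` implements this pipeline as
composable, file-based stages with a seeded synthetic-data module, so the
whole procedure is testable without access to the proprietary databases
and omics repositories it is normally run against.

## Target assembly

Predicted compound-target records carry a pharmacophore-style score.
Per compound, records with score strictly above `score_min` (default 60)
are kept; when no record clears the cut, the `top_k` (default 50)
highest-scored records are kept instead — the two rules act as
alternatives, mirroring the "score above threshold *or* best-ranked"
convention of pharmacophore servers. Curated records without a score pass
unfiltered. Note a consequence of the fallback: raising `score_min` is
not globally monotone, because emptying a compound's strict set
re-admits its `top_k` best records. Disease-side sets from several
sources are merged by union with per-symbol source provenance.

Symbols are compared after trimming and uppercasing (the human-symbol
convention). Ortholog translation (`map_orthologs`) matches its source
side on *case-preserved* symbols first, because mouse symbols are
case-significant; a case-insensitive fallback is applied only when
unambiguous, and outputs are then normalized.

## Differential-expression screen

Per gene, a two-sided two-sample t-test on log2-scale values — Welch's
unequal-variance form by default, which is the standard choice for small
two-group microarray comparisons; Student's pooled form is available. The
log2 fold change is the case-group mean minus the control-group mean
(the fold-change ambiguity of linear-versus-log averaging is resolved as
a difference of log2 means). Thresholds are strict: microarray mode keeps
`|log2FC| > 1` and `p < 0.05`; RNA-seq mode keeps `|log2FC| > log2(1.5)`,
i.e. fold change above 1.5 in either direction. Raw p-values are used by
design — the screen is a recall-oriented filter whose output is
intersected across datasets, which is itself a stringent conjunction;
Holm/Bonferroni/BH correction is available but off by default. Degenerate
genes follow fixed conventions: zero variance in both groups gives
`p = 1` at equal means and `p = 0` otherwise (logged). The multi-dataset
Venn intersection reports the genes common to all datasets plus the size
of every exclusive membership region.

A negative-binomial count model is deliberately out of scope: RNA-seq
input is expected as `log2(count + 1)` and screened with the same test.

## Interactome projection and the six centrality indices

Target sets are expanded against a user-supplied interactome by
seed-plus-first-neighbour expansion (depth configurable) with induced
edges, the behaviour that reproduces the order-of-magnitude growth seen
when a few hundred seeds yield several-thousand-node networks. Drug-side
and disease-side subnetworks are intersected node-wise and edge-wise.

On the intersection, six indices are computed per node `v` of the simple
undirected graph:

* **DC** — degree.
* **BC** — betweenness, `sum over pairs s<t of sigma_st(v)/sigma_st`,
  unnormalized over unordered pairs (Brandes accumulation).
* **CC** — closeness, `(n_c - 1) / sum of d(v,u)` over `v`'s connected
  component of size `n_c`; isolated nodes get 0.
* **EC** — eigenvector centrality: the nonnegative principal eigenvector
  of the adjacency matrix, computed per connected component with unit
  Euclidean norm; nodes of edgeless components get 0.
* **LAC** — local average connectivity: the mean, over `v`'s neighbours,
  of their degree within the subgraph induced on those neighbours.
* **NC** — the sum over incident edges of the edge clustering
  coefficient `ECC(u,v) = |N(u) ∩ N(v)| / min(DC(u)-1, DC(v)-1)`,
  defined 0 when the denominator is 0.

EC uses shifted `(A + I)` power iteration with a deterministic uniform
start (tolerance `1e-12` on the sup-norm step, at most 10,000
iterations); the shift guarantees convergence on bipartite components,
where plain power iteration oscillates. Setting EC to 0 on edgeless
components (rather than assigning the trivial unit vector) keeps the
degenerate single-node hub network self-consistent in the screen below.

## Two-stage median-multiple screen

Stage 1 computes DC on the input network and keeps nodes with
`DC >= multiplier x median(DC)` (multiplier 2 by default, comparisons
inclusive; even-length medians are midpoint averages). The induced
subgraph is the *hub network*. Stage 2 recomputes all six indices on the
hub network — not inherited from the full network, consistent with
second-stage degree cutoffs that exceed first-stage ones on denser
subnetworks — and keeps nodes at or above `multiplier x median` of every
index; the induced subgraph is the *core network*. An empty stage-1
result is an error with a diagnostic summary of the degree distribution.

**A scale limitation worth knowing.** Closeness is bounded by 1 and, on a
*connected* hub network whose pairwise distances all fall in a narrow
band (as they do on compact, rich-club-like hub networks derived from
preferential-attachment graphs), `max(CC)` never reaches
`2 x median(CC)`; the closeness criterion is then unattainable and the
core network is empty. At the scale of real curated interactomes the
screened networks have a much wider closeness spread and non-empty cores
are reported. The default synthetic run therefore demonstrates the full
machinery (thresholds, tables, nesting invariants) with an honest,
possibly empty, core at multiplier 2; `multiplier = 0` degenerates to
keeping everything, which the tests use to exercise the downstream
stages.

## Over-representation and kappa grouping

Enrichment of a query set against a GMT library is the exact upper-tail
hypergeometric probability (one-sided: over-representation only, since
only enriched pathways are interpreted). The universe defaults to all
genes annotated in the library and is configurable to the interactome
node set. Correction defaults to Holm (the step-down Bonferroni familiar
from ClueGO-style tools); Bonferroni and Benjamini-Hochberg are options.

Significant terms (`p_adj <= 0.05`) are grouped by the kappa statistic of
their query-hit memberships: with `a` shared hits, `b` and `c` exclusive
hits and `d` query genes in neither term,
`kappa = (po - pe) / (1 - pe)` with `po = (a + d)/q` and
`pe = ((a+b)(a+c) + (c+d)(b+d))/q^2`, and `kappa = 1` when `pe = 1`.
Terms with pairwise `kappa >= 0.4` are linked and groups are the
connected components (single linkage) — simpler and fully deterministic
compared with iterative leading-group merging, and faithful to the only
published constraint, the kappa threshold itself. The kappa universe is
the query set (the membership universe of a ClueGO-style binary
gene-term matrix is ambiguous; the query is the defensible choice since
only query genes are observed in both terms). Each group's leading term
has the smallest adjusted p, ties broken by larger hit count, then
lexicographic id.

## Synthetic study conditions

The generators are pure functions of `(config, seed)` and default to the
conditions the pipeline is designed around:

* **Interactome**: preferential attachment, n = 2,000 nodes, m = 2 edges
  per arrival (scale-free, so the median-multiple screen has hubs to
  find), plus 20 planted *superhubs* boosted until each is adjacent to
  15% of the network. The fraction-based boost emulates the TP53/UBC
  class of curated-interactome hubs, whose neighbourhoods span between
  roughly a sixth and two thirds of all nodes; a multiple-of-median
  boost would produce hubs far below that regime.
* **Expression**: five datasets (mirroring a five-cohort microarray
  comparison), 1,000 genes drawn from the interactome, 10 case and 10
  control samples each, Gaussian log2 intensities with baseline mean 8
  and unit standard deviation; 100 planted differential genes per
  dataset at `|log2FC| = 2` (random sign), of which 66 are shared across
  all five datasets — the scale of the shared-DEG set the pipeline is
  designed to recover.
* **Evidence tables**: 22 compounds (one formula's serum-absorbed
  constituents) across 10 herbs, about 18 targets each; half the records
  curated (unscored), half scored uniform on [40, 100]; 150 disease
  targets of which 40% overlap the drug-target pool, labelled with five
  database-style sources.
* **Gene-set library**: 41 background terms of 10-40 genes drawn
  uniformly from the universe, plus one planted term of 20 genes, 15 of
  them inside a designated 50-gene query (the planted hubs plus a seeded
  sample of their neighbours — a core-target-sized set; using the entire
  hub neighbourhood would approach the whole universe and make
  over-representation degenerate).

What the generators do *not* emulate: probe-level noise, normalization
artifacts and batch effects; count overdispersion; correlated gene
modules; literature bias of curated interactomes; modular community
structure (see the closeness note above). Passing tests therefore
establish algorithmic correctness and calibration under clean Gaussian
and preferential-attachment assumptions, not performance on real data.

## Numerical and degenerate-input choices

* Self-loops are dropped and duplicate (including reversed) edges
  collapsed on input; the centrality definitions assume simple graphs.
* Edge and node tables are emitted in canonical sorted order with `#`
  comment headers, so equal networks produce byte-identical files and
  every writer/reader pair round-trips exactly.
* Zero-length edge sets are handled explicitly (R's `paste0`/`order`
  misbehave on zero-length input).
* Duplicate gene rows in an expression matrix keep the highest-mean row.
* `threshold_degs` preserves symbol case by default so mouse DEGs can be
  ortholog-mapped afterwards.
* All randomness flows through explicit integer seeds; every pipeline
  artifact is byte-identical across reruns with the same configuration.

## Problem sizes used by the test-suite

Unit and property tests run on graphs of 5-100 nodes against closed
forms, exhaustive enumeration and an independent graph library; screening
self-consistency and planted-hub retention use twenty 2,000-node
attachment networks; DEG calibration uses 2,000 genes at 10 + 10 samples;
Monte-Carlo checks of the hypergeometric tail use 100,000 resamples per
configuration. The end-to-end pipeline runs the default conditions above
in a few seconds.
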