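---
title: "Statistical methods behind associome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods behind associome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(associome)
```

## The model

`associome` treats a disease–gene knowledge base as a heterogeneous
network with two layers: a bipartite disease–gene association layer and a
typed gene–gene interaction layer. Two diseases are molecularly related
to the extent that (a) their associated gene sets overlap, and (b) the
overlapping genes are wired together. Both effects are tested with
empirical permutation nulls; nothing is assumed about the distribution of
set sizes or degrees.

### Relation indices and their null

For gene sets $A$ and $B$ of two diseases:

$$I_{AB} = |A \cap B|, \qquad
  J_{AB} = \frac{|A \cap B|}{|A \cup B|}, \qquad
  M_{AB} = \frac{|A \cap B|}{\min(|A|, |B|)}.$$

$I$ is raw sharing, $J$ normalises by the union (penalising very unequal
sets), $M$ by the smaller set (so a small disease fully contained in a
large one scores 1). Always $0 \le J \le M \le 1$. Degenerate cases
return `NA` rather than 0 — $J$ when both sets are empty, $M$ when either
is — so that undefined replicates can be excluded from a null instead of
silently deflating it. In practice diseases with no associated genes are
ineligible for the null anyway, mirroring the usual curation step in
which disease vocabularies carry many entries with no known protein.

The null distribution is built by drawing unordered pairs of distinct
eligible diseases uniformly at random (`relation_index_null()`). The
default replicate count is 10,000; desk-scale analyses in this package's
tests use 2,000, which resolves p-values to 0.0005. The empirical
p-value of an observed index is the proportion of null replicates with
the *same or larger* value. This tie convention means p can be exactly 0;
an optional `tie = "add_one"` convention reports $(k+1)/(n+1)$ instead,
which never reaches 0 and is the better choice when p-values feed further
inference. The default reproduces the proportion convention common in
permutation testing of network overlap.

### Degree-matched connectivity null

Whether comorbid genes interact more than chance cannot be judged against
uniformly random gene sets: well-studied genes have more recorded
interactions, and comorbid genes are well studied. The null therefore
controls for degree. For each vertex $i$ of the analysed gene set, the
candidate set $Q_i$ contains every knowledge-base gene whose interaction
degree equals that of $i$ (`build_q_sets()`). One random network draws
one gene per vertex from its $Q_i$, all distinct within the replicate,
and inherits every knowledge-base interaction between the sampled genes.
The observed connectivity is compared with `n` such networks (default
1,000; tests use 300) under the same same-or-larger convention.

Choices worth making explicit:

* **Degree counts distinct partners**, not link records, because a pair
  of nodes may carry several typed links and record-counting would make
  $Q_i$ membership depend on annotation redundancy. Record-based degree
  is available via `count = "records"`.
* **Direction is ignored** for degree and connectivity; it is preserved
  in storage for reporting.
* **Two connectivity statistics** are always computed side by side: the
  number of distinct connected pairs and the number of link records. They
  differ exactly when multi-typed links exist; connected pairs is the
  default test statistic, link records the alternative (`stat = "links"`).
* **$Q_i$ can never be empty** for a template gene present in the
  knowledge base (the gene matches its own degree). If a degree class is
  ever empty — possible only for externally supplied templates — the set
  widens to the nearest available degree, ties toward the smaller degree,
  and the vertex is flagged; this keeps small knowledge bases usable
  without changing the exact-match semantics silently.
* **The template's own genes are not excluded** from their $Q_i$, so the
  analysed network itself is a valid draw; this makes the null
  conservative rather than anti-conservative.
* **Small universes limit power.** In a knowledge base where the analysed
  genes are almost the only ones of their degree, random networks
  resample the analysed set and the p-value tends to 1. That is the
  correct answer to the question being asked ("is this wiring unusual
  *at this degree*?"), and the reason benchmarks here use universes of
  1,500 genes where high-degree classes have dozens of members.

### Enrichment and the connectivity rate

Overrepresentation of annotation terms in a study set uses the exact
hypergeometric upper tail $P(X \ge k)$ (via `stats::phyper`) with the
whole annotation as the reference universe, and Benjamini–Hochberg
q-values over all tested terms (via `stats::p.adjust`). Terms with no
study gene are not tested. The adjusted values satisfy the step-up
monotonicity in sorted-p order; note that re-feeding q-values through the
adjustment is *not* an identity (the multiplicity factor would be applied
twice) — the stable property, which the tests assert, is that the
monotonicity pass is a fixed point of its own output.

The **connectivity rate** of a gene group in an analysed network is the
fraction of its $\binom{g}{2}$ possible pairs directly linked
(`connectivity_rate()`); it is undefined (`NA`) for groups of fewer than
two genes. Ranking enriched terms by CR (descending, ties by ascending
q-value then term id, undefined CRs last — a deterministic rule chosen
for reproducible reports) surfaces small, tightly wired processes that a
pure p-value ranking buries under huge generic terms. GO true-path
propagation is not performed; annotations are used as supplied, so
pre-propagated inputs behave as in propagating tools.

### Pathway pattern search

`find_pathways()` enumerates the *complete* set of chains matching a
node-class pattern, by construction: candidate sets per slot, edge-join
along the chain, interior-gene distinctness, lexicographic output order.
Disease–gene steps must be supported by association records, gene–gene
steps by interaction records of any type (restrictable via
`link_types`). Gene/protein duality is honoured by label propagation: a
labelled gene's protein node satisfies the same slot, and matches report
the concrete node used. Correctness is checked against brute-force
five-tuple enumeration on 50 random knowledge bases. Matches are merged
into a deduplicated union network whose node and link counts are
invariant to match order.

## The synthetic generator

`generate_kb()` emulates the statistical structure the analysis assumes,
not any real database's content:

* **Association-set sizes** are log-normal (default meanlog
  $\log 12$, sdlog 1), giving the heavy tail real disease vocabularies
  show — most diseases with a handful of genes, a few with hundreds. One
  property test swaps in near-constant sizes to confirm no stage depends
  on the family.
* **The interaction graph** is a configuration model with discrete
  power-law degrees (exponent 2.5, degrees 1–60, mean degree ≈ 2.2),
  built by stub pairing with self-loops and duplicate pairs erased. Link
  types are drawn from a categorical distribution dominated by
  association and expression links, and 15% of connected pairs carry a
  second typed link, so pair counts and record counts genuinely differ.
* **Planted comorbidity**: each planted pair adds a shared gene pool to
  both diseases; pairs may name a common pool, so several pairs plant one
  multi-disease comorbid set. Interconnectivity is raised to `rho` by
  rewiring randomly chosen background edges onto unlinked pool pairs —
  the total connected-pair count is preserved, so the degree-matched null
  stays honest (the pool's degrees rise, and the null sees the risen
  degrees).
* **Planted terms** draw a stated fraction of their genes from a planted
  pool, the rest uniformly.

What the generator does *not* emulate: gene-level ascertainment bias
beyond degree, correlated annotations (terms are drawn independently),
literature redundancy, or directionality structure. Passing tests on
synthetic data therefore demonstrate correctness of the statistics and
machinery, not performance on any real knowledge base.

## Problem sizes and benchmark conditions

The package's own benchmark conditions, used by the test suite and
`scripts/acceptance.R`, are: 60 diseases and 1,500 genes; three planted
pairs over one 25-gene pool with `rho = 0.3` (so the pool is the 3-way
comorbid set of its diseases); a 2,000-replicate random-pair null; a
300-replicate degree-matched connectivity null; calibration on a
no-signal knowledge base with 100 probed pairs; and 20 generator seeds
for recovery, of which at least 19 must flag every planted pair at
p ≤ 0.05 on $I$ and $J$ and the pool at connectivity p ≤ 0.01. Exhaustive
oracles (all degree-matched assignments of a 12-gene knowledge base; all
hypergeometric configurations up to $N = 12$; brute-force pathway
enumeration) pin the Monte-Carlo and vectorised implementations to first
principles. Under these sparse background conditions complete five-node
pathway chains are rare and often absent; the pathway stage's value on
such inputs is the exactness of its enumeration, not the size of its
output.

## Determinism and degenerate inputs

Every stochastic function takes an explicit seed and restores the
caller's RNG state; `run_full_analysis()` refuses configurations without
one, stages its outputs in a temporary directory (no partial bundles on
failure), and produces byte-identical bundles for identical
configuration and seed — writers sort all tables in C-locale radix order
to keep files stable across platforms. Degenerate inputs are either
errors (empty templates, fewer than two eligible diseases, analysed sets
smaller than two genes) or `NA`s that propagate visibly (undefined $J$,
$M$, CR), never silent zeros.

## Known limitations

* Empirical nulls only: no analytic approximations, so p-value resolution
  is $1/n$ and tails cost replicates.
* Exact-degree matching can be restrictive in small or very sparse
  universes (see above); the nearest-degree fallback is a pragmatic
  widening, not a calibrated coarsening.
* No gene-identifier normalisation or synonym resolution; ids are opaque
  case-sensitive strings.
* GO ancestry is not propagated from an ontology file; supply
  pre-propagated annotations for BiNGO-like behaviour.
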