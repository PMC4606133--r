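---
title: "Discovering distinct functional modules across labeled PPI networks"
author: "distinctmods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering distinct functional modules across labeled PPI networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(distinctmods)
```

## The problem

Comparative interactomics asks which parts of a protein–protein interaction
(PPI) network are peculiar to one condition. Given several undirected
networks over a shared protein namespace — in the motivating application,
one network per cancer type, built by intersecting differentially expressed
genes with a reference interactome — we want the functional modules that
exist in exactly one network: first as concrete *distinct subgraphs*
(identified by their actual nodes and edges), then as *distinct subgraph
patterns*, where node identities are abstracted to cluster labels so that
near-identical proteins count as the same actor. Patterns are the stricter
notion: a subgraph unique by its node content is still not pattern-distinct
if another network contains a same-labeled, same-topology subgraph.

This vignette documents the model, the tunable parameters, the numerical
choices, and what the synthetic test bed does and does not establish.

## Stage 1: module detection by restricted neighbourhood search

Each network is partitioned into non-overlapping clusters by a tabu-assisted
local search (RNSC). Two cost functions drive the search. The **naive cost**
of a partition is

$$C_n = \sum_{v \in V} \Big( |N(v) \setminus C(v)| + |C(v) \setminus N(v) \setminus \{v\}| \Big),$$

the per-vertex count of misplaced connections: neighbours outside the
vertex's cluster plus non-neighbour co-members. The **scaled cost** divides
each vertex's term by the size of its relevant neighbourhood
$|C(v) \cup N(v)|$ and multiplies the sum by $|V|/3$, de-emphasizing large,
sparse clusters. The original RNSC description defers the exact functional
forms to its implementation; the forms above are this package's fixed,
documented choice, and `rnsc_cluster` is deliberately just one implementation
of the `Graph -> Partition` contract — any clustering (including the original
C binary's output, via `load_label_map`-style ingestion of assignments) can
be substituted upstream of module extraction.

The search runs the naive phase to its stopping tolerance, then the scaled
phase, from a uniformly random initial assignment to $\lfloor\sqrt{|V|}\rfloor$
clusters. Moves relocate a single vertex to an adjacent cluster or to a fresh
singleton; the best move (ties broken by ascending vertex index, then target
cluster id, fresh singleton last) is accepted even when it worsens the cost,
with the best-so-far partition retained. A tabu list of the last
`tabu_length` moved vertices forbids vertices appearing at least
`tabu_tolerance` times; when every movable vertex is tabu the best move is
taken regardless, so the search cannot stall. Every
`diversification_frequency` steps a shuffling diversification relocates
`shuffling_diversification_length` random vertices (the destructive
alternative is intentionally not implemented, since setting a shuffling
length selects shuffling). Defaults are the published settings: tolerance 1,
length 50, stopping tolerances 15 and 15, frequency 50, shuffling length 3.

Two design choices are this package's own:

* **Per-component search.** Neither cost function ever rewards a cluster
  spanning two connected components (merging components can only add
  non-neighbour penalties), so the graph is clustered one component at a
  time. Besides speed, this buys a useful purity property: the RNG stream of
  each component is seeded from the global seed plus a checksum of the
  component's canonical label, so the clustering of a component depends only
  on its content. Identical components appearing in several networks — the
  common backbone of a comparison set — therefore receive identical
  partitions, which is what makes cross-network module comparison meaningful
  rather than an artifact of search stochasticity.
* **Incremental bookkeeping.** Cost deltas are maintained incrementally in
  the C++ search; a debug mode recomputes the full cost after every accepted
  move and reports the largest discrepancy (asserted to be ~0 in the tests).

Module extraction takes each cluster's node-induced subgraph and emits its
connected components; single-node and other sub-threshold modules are kept
here and filtered at the next stage.

## Stage 2: distinct subgraphs via canonical labels

A graph's canonical label is its node list in ascending lexicographic
(C-locale) order followed by the upper-right triangle of the adjacency matrix
under that order, one bit per node pair. Any fixed total order satisfies the
uniqueness requirement; lexicographic is chosen for determinism, and the
label is provably invariant to input order because graph construction
normalizes nodes and edges first. Self-loops are rejected at construction
(the triangle excludes the diagonal); duplicate edges collapse silently.

Per network, a hash table maps canonical keys to modules. A module of network
$N$ with at least `min_edges` (default 3) edges is a **distinct subgraph**
when (i) its key is absent from every other network's table and (ii) its
edge set is not a subset of any other module's edge set. The enclosure test
spans modules of *all* networks including $N$'s own: with node-disjoint RNSC
clusters same-network enclosure cannot occur, so the choice is inert there,
but it keeps the filter correct under pluggable clusterers that may emit
overlapping modules. Enclosure compares edge sets only, implemented as an
intersection over an inverted edge-to-module index.

## Stage 3: distinct patterns via the edge-pattern index

Subgraph patterns abstract node identities to labels; an edge pattern
`A–B (c)` is an unordered label pair with its multiplicity. Three structures
index the candidate universe (all modules of each network): subgraph → edge
patterns; the reverse index edge pattern → subgraphs; and, for each pattern
`A–B (c)`, the expanded patterns `A–B (k), k > c` present in the index, which
let a query match inside larger supergraphs. Candidates for a query are the
intersection, over the query's edge patterns, of the reverse-index unions
over each pattern and its expansions, after dropping subgraphs with fewer
nodes or edges than the query. The filter is sound — it never drops a true
embedding target — so an empty candidate set proves pattern distinctness
outright.

Non-empty candidate sets are verified by one of two matchers:

* `paper_greedy`: seed at the query node of highest degree, then repeatedly
  extend to the unmatched query node of highest degree among those adjacent
  to matched nodes; a counterpart must carry the same label and cover the
  already-matched adjacencies; the first compatible counterpart is taken and
  the search halts, without backtracking, on the first unmatched node. Ties
  (equal degrees, multiple counterparts) break by node-identifier order —
  the original description leaves both unspecified. This matcher is fast but
  incomplete on symmetric candidates, and the test suite pins a concrete
  counterexample where it misses a real embedding.
* `exact` (default): full backtracking label-preserving subgraph isomorphism.
  Exactness is what the planted-recovery guarantees below are stated against,
  which is why it is the default; the greedy matcher remains available behind
  the `mode` flag for fidelity and speed comparisons.

A query pattern is distinct when every other network yields no verified
candidate. Distinct subgraphs of one network sharing a pattern key (label
multiset plus labeled-edge multiset) collapse into one distinct pattern with
several witnesses.

## Node labeling

Labels come either from a user-supplied protein → cluster TSV or from a
greedy, longest-first sequence clustering in the CD-HIT style: each sequence
joins the first cluster whose founding representative aligns at ≥90% identity
over ≥95% of the length of *both* sequences (the stricter reading of
"each sequence"), under a global alignment with unit match/mismatch/gap
scores; otherwise it founds a new cluster. Identity is computed over the
both-residue alignment columns, coverage as those columns' share of each
sequence's length. The pipeline consumes only the partition, so any external
clustering tool can substitute.

## GO semantic scoring

Term probabilities are Resnik-style annotation frequencies computed from the
supplied GAF (the probability corpus is not prescribed by the source method):
$p(t)$ is the fraction of a concept's annotations hitting $t$ or any
descendant, so the root has probability 1 and $p$ is monotone along the DAG.
For two term sets, $P_{ms}$ is the probability of the least frequent shared
ancestor, with ancestors computed *inclusively* (a term is its own ancestor —
otherwise identical terms would be penalized), and similarity is
$-\ln P_{ms}$ per concept. Disjoint sub-DAGs return $P_{ms}=1$ with a
warning. A protein pair's total score sums the per-concept bests and is
clamped to the reported 0–10 range (the clamp interpretation of that range;
unclamped per-concept values are also returned). Group scores for an
$n$-edge size class are the flat mean over all edges of all subgraphs in the
class (mean chosen where the aggregation statistic is unstated), and the null
comparison draws seeded random *connected* edge-grown subgraphs of the same
edge count from the same network.

## Validation statistics

The edge overlapping rate of a subgraph against a reference network is the
fraction of its edges present in the reference (undirected). Per reference,
the rates of the same-condition distinct subgraphs are compared to each other
condition's rates with a one-sided t-test (alternative: same-condition mean
is larger). Welch's unequal-variance statistic is the default — the source
method says only "one-sided t-test" — with the pooled Student variant behind
`var_equal = TRUE`. Subgraphs with zero overlap are included in their groups.
When both groups are numerically constant the statistic is degenerate; the
convention is p = 0.5 at equal means (flagged), 0/1 otherwise by sign.
No multiple-testing correction is applied, matching the source analysis.

## The synthetic test bed

`generate_ensemble` emulates a comparison set over a shared namespace: one
Erdős–Rényi background (default edge probability 0.028) and five shared
clique modules (sizes 3, 4, 4, 4, 5) are *identical* — same node identifiers,
edges and labels — across all nine networks, while each network receives
three unique clique plants (sizes 3, 4, 5) on fresh node identifiers wired
as separate components, each carrying a reserved per-network label. Defaults
give ~300 nodes and ~1,000 edges per network. A post-generation audit runs
the exact oracle to confirm no unique pattern embeds in any other network,
resampling (bounded) otherwise. Ground truth is machine-readable and consumed
directly by the acceptance tests; `generate_reference` builds matched
validation references embedding a deterministic fraction of each unique
plant's edges plus noise edges disjoint from every network, and
`generate_toy_go` emits tree-shaped ontologies whose term probabilities are
known in closed form alongside the OBO/GAF text.

What passing on this bed shows — and what it does not. The plants are dense
cliques disconnected from the background, so exact recovery demonstrates the
correctness of the filtering, indexing and matching machinery and the
determinism of the search, not RNSC's ability to carve fuzzy modules out of a
scale-free interactome: real PPI degree distributions, inter-module edges and
annotation noise are deliberately not emulated. On real data the clustering
stage, not the distinctness machinery, is the accuracy bottleneck, and the
pluggable-partition interface exists for exactly that reason.

## Numerical and degenerate-input choices

* Ordering is C-locale (radix) throughout; artifacts are byte-reproducible
  for a fixed config and seed, and timestamps appear only in `run.log`.
* All RNG flows through R's generator (including inside the C++ search), so
  one integer seed governs a run; per-component seeds derive from it via a
  content checksum (collisions are harmless — the value only seeds a stream).
* Degenerate inputs: empty graphs refuse clustering; single-vertex and
  two-vertex components cluster trivially; edgeless modules are legal until
  the `min_edges` filter; empty label maps load with a warning; a duplicated
  protein id is an error, never a silent overwrite; an empty scoring group is
  an error rather than NaN.
* Problem sizes in the shipped tests (10,000 graphs × 100 permutations for
  canonical labels, 1,000 matcher-oracle pairs, one 9-network ensemble run
  for recovery and two for byte-identity, 30 random subgraphs per edge-count
  group) were chosen to exercise the properties at the study's scale while
  keeping a full suite run in the minutes range on one CPU.

## Known limitations

* The greedy matcher is knowingly incomplete; exactness costs worst-case
  exponential time, acceptable here because the index filter leaves few
  candidates, but potentially slow on pathological label-homogeneous inputs.
* Canonical labels identify graphs by node identity, not isomorphism class —
  sufficient for distinct-subgraph hashing, by design not a nauty-style
  canonical form.
* Pattern keys (label multiset + labeled-edge multiset) can in principle
  collide for non-isomorphic graphs with heavily repeated labels; witnesses
  are verified by embedding before any collapse, so collisions can only
  merge reports, not create false distinctness.
* Sequence clustering is quadratic greedy alignment, intended for the
  moderate protein sets of a comparison study, not proteome-scale input.
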