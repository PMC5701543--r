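---
title: "Median-threshold key-target analysis for multi-compound interventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Median-threshold key-target analysis for multi-compound interventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netpharm)
```

## The model

A multi-compound preparation is represented by the bipartite relation
between its compounds and their predicted (putative) protein targets; each
disease by the set of its known therapeutic targets, merged by plain set
union across source databases and deduplicated after symbol normalisation
(uppercase, whitespace-trimmed — no alias resolution, because none can be
done deterministically without an external mapping service). The analysis
graph is the *target-anchored* PPI: its nodes are the union of putative and
therapeutic targets, its edges the input protein–protein interactions with
both endpoints in that set. Interactions between two non-target proteins
are deliberately excluded — the object of study is the intervention's
target neighbourhood, not the whole interactome.

Key targets are defined purely topologically, in two stages:

* **Stage A** removes every node whose degree is below `multiplier` times
  the median degree of all nodes (default 2) and rebuilds the induced
  subgraph (the *hub network*). We read "deleted the nodes that had degree
  values of less than 2-fold the median" literally, so a node sitting
  exactly at the threshold is kept.
* **Stage B** recomputes degree, betweenness, closeness and core number on
  the hub network — never reusing stage-A values, since every induced
  subgraph changes all four features — and keeps the nodes strictly greater
  than all four medians.

Strict inequality in stage B is not a detail: on any vertex-transitive
graph every node ties every median and the key-target set is correctly
empty, and on every graph with more than one node at least one node fails
at least one feature, so the filter is always a strict contraction.

A consequence worth knowing: stage A is *not* idempotent under a frozen
threshold. Deleting low-degree nodes removes their edges, so survivors can
drop below the old threshold in the hub network (two hubs joined to each
other and to five leaves each survive at threshold 2 but have degree 1
afterwards). The filter is a one-shot procedure by design; re-application
is a different analysis.

### Feature conventions

The four features are computed from first principles on the undirected,
unweighted simple graph:

* *Betweenness* follows Brandes' dependency accumulation, unnormalised,
  with each unordered pair counted once and disconnected pairs contributing
  zero. Unnormalised values are the convention under which published
  feature medians of this kind (tens, not fractions) are interpretable.
* *Closeness* is `1 / sum(d(v, u))` over the nodes reachable from `v`.
  This inverse-distance-sum convention (rather than `(n-1)/sum d`) matches
  the magnitude of closeness medians reported in this literature
  (~1/300 on networks of a few hundred nodes) and is the classical igraph
  behaviour; on disconnected graphs it is computed per component, and an
  isolated node gets 0. The choice is recorded in the topology profile and
  a user comparing against another tool should check which normalisation
  that tool applies.
* *Core number* is by iterative minimum-degree peeling.
* Every median, including the docking-score median, is the
  linear-interpolated sample median (mean of the two middle order
  statistics for even n). Published medians of float-valued features in
  this field are non-integers, which is only consistent with the
  interpolated convention; we apply it uniformly rather than mixing
  conventions per feature.

Correctness is established two independent ways in the test suite: against
exhaustive brute-force oracles (all-simple-paths enumeration,
Floyd–Warshall, all-subgraphs minimum-degree search) on hundreds of random
graphs with up to 8 nodes, and against `igraph` on larger random graphs.
`igraph` is never used to *compute* the analysis.

### Topology on the protein-only graph

Compound nodes and per-disease "source" nodes can be attached to the
network for export and visualisation (`include_source_nodes = TRUE`), but
all topological features are computed on the protein–protein subnetwork.
Attaching 20-odd compound hubs would dominate degree and betweenness and
turn the key-target filter into a compound detector; reported feature
medians in this literature are consistent with protein-only graphs. Users
who want the alternative reading can compute `topology_profile()` on the
full exported network themselves.

## Enrichment

Over-representation uses the hypergeometric upper tail,
`P(X >= k)` for `X ~ Hypergeom(N, K, n)`, evaluated by summing
`exp(lchoose(...))` terms in log space — stable down to the q ≈ 1e-300
range, and checked to 1e-12 against exhaustive enumeration of all draws for
small universes. The significance filter is the raw `p < alpha` cut-off
(default 0.05), which is the criterion this style of analysis states;
Benjamini–Hochberg q-values are computed across all overlapping sets (via
`stats::p.adjust`) and reported alongside so that users can apply FDR
control instead. The default universe is the union of all genes annotated
in the collection — the standard ORA default — and can be overridden with
an explicit background. Sets with zero overlap are dropped: they carry no
p-value of interest and no edges in the pathway–target network, whose edge
count always equals the summed overlap sizes.

Under a global null (random query, decoy-only collections) the fraction of
collections yielding any q < 0.05 call is bounded by the nominal 0.05; the
hypergeometric's discreteness makes it conservative in practice (~0.03 in
the seeded simulation the tests run, 1,000 replicates).

## Docking filter

Docking is ingested, never computed. Duplicate (compound, target) rows
collapse to their maximum score *before* the median is taken — docking
scores are best-pose scores, and computing the median over redundant poses
would let one heavily re-docked pair shift everyone's threshold. Retention
is strictly above the median of all deduplicated scores, so with n distinct
scores and odd n exactly (n−1)/2 pairs survive, and rescaling all scores
leaves the retained set unchanged. The threshold is always data-derived;
no published median value is hard-coded.

## What the synthetic generator emulates — and what it does not

`simulate_bundle()` produces every pipeline input at the study scale the
analysis assumes by default: 20 compounds with 97 putative targets;
therapeutic-target lists of 59, 279 and 20 symbols for T2D, HT and HL; the
planted Venn regions of `default_region_spec()` (8 putative targets shared
with HT only, 1 with HL only, one symbol in each triple region, one shared
by all four sets — 13 disease-related putative targets in total, the
arithmetic that reproduces the published four-set diagram); redundant
disease-target rows (double source listings, case variants) so
deduplication has real work; Gaussian docking scores with median at the
`docking_mean` default of 86, the magnitude of published LibDock medians.
Symbols are synthetic `G000001`-style tokens and compounds `CPD0001`-style,
deliberately avoiding real identifiers so no file can be mistaken for a
biological claim. One master seed fans out to fixed per-table child seeds;
bundles are byte-identical per seed.

Two PPI generators serve different purposes:

* `simulate_ppi()` draws a preferential-attachment graph
  (via `igraph::sample_pa()`) and emulates the heavy-tailed degree
  distribution of merged PPI snapshots (max degree ≥ 20× the median at
  n = 10,000). It has no key-target ground truth: under preferential
  attachment the two-stage filter's output is real but unknowable a
  priori.
* `simulate_hub_network()` is the designed three-tier topology the bundle
  uses: a clique of `n_hubs` hubs (each also tied to mid-tier nodes), a
  cycle of `n_mids` mid-tier nodes each tied to exactly two hubs
  (balanced round-robin, so no hub is left without a mid-tier tie and a
  zero-betweenness hub cannot occur), and degree-1 pendants on random
  mid-tier nodes. The parameter constraints (`n_hubs >= 6`,
  `n_mids >= n_hubs + 2`, `n_pendants >= n_hubs + n_mids + 2`) are exactly
  what makes recovery provable: pendants hold the network-wide median
  degree at 1 so stage A keeps precisely hubs + mids; mid-tier nodes then
  all have hub-network degree 4, which *is* the median, so the strict test
  removes every one of them; and the hub clique's core number
  (`n_hubs − 1 >= 5`) strictly exceeds the mid-tier 4-core. The planted
  hubs are therefore the exact key-target set — verified across dozens of
  seeds in the tests, not assumed.

What passing on these bundles does **not** show: real PPI networks have no
clean tier structure, real disease lists have correlated annotation biases,
real docking scores are not Gaussian, and symbol normalisation on real data
has to contend with aliases. The synthetic results validate the
*machinery* — that the filters, counts and tests compute what they claim —
not any biological conclusion.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `stage_a_multiplier` | 2.0 | stage-A degree cut as a multiple of the median degree (dimensionless); 2-fold is the published convention this workflow follows |
| `alpha` | 0.05 | raw-p enrichment cut-off |
| `include_source_nodes` | `FALSE` | attach compound/disease nodes for export (never for topology) |
| `docking_mean`, `docking_sd` | 86, 25 | synthetic docking-score distribution (dimensionless LibDock-like scale) |
| `n_hubs`, `n_mids` | 7, 12 | planted hub-network tiers; remaining proteins become pendants |

## Problem sizes and determinism

The default bundle yields a 437-protein network; a full pipeline run takes
a few seconds, dominated by the O(nm) betweenness pass. The test suite
exercises oracle equivalence on 200 random graphs of up to 8 nodes (where
exhaustive enumeration is exact), recovery on ~25 hub-network seeds, and
1,000 null-ORA replicates — sizes chosen so every claim is checked
exactly rather than spot-checked. The pipeline itself contains no
randomness: identical inputs and configuration give byte-identical outputs,
which the tests verify by hashing entire output directories.

## Known limitations

* No identifier mapping: two databases naming the same protein differently
  yield two nodes. Normalisation is case/whitespace only, by design.
* Betweenness is exact, not approximated, so very large PPI snapshots
  (10^5+ nodes) would need the stage-A cut applied on degree first or an
  approximate-betweenness extension.
* The enrichment module is ORA only — no rank-based (GSEA-style)
  statistics.
* SIF export cannot carry node annotations; use GraphML when round-tripping
  attributes matters.
* Published headline counts from any particular study depend on that
  study's database snapshots (PPI merge, pathway collection, docking
  table) and are not reproducible from code alone; the package reproduces
  the *procedure* and validates it on planted ground truth.
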