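---
title: "Profile networks, modularity classes, and TNCS candidate ranking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profile networks, modularity classes, and TNCS candidate ranking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(profnet)
```

`profnet` ranks drug repurposing and repositioning candidates by their
structural influence within a disease-profile network carved out of a
heterogeneous biomedical knowledge graph. This vignette is the package's
account of the method: the model and its assumptions, the parameters that
matter, the numerical choices made where the procedure is underdetermined,
and what validation on synthetic graphs does and does not establish.

## The graph model

A knowledge graph here is a directed, typed multigraph. Nodes are biomedical
concepts — diseases, genes, drugs, phenotypes, or other entities — carrying
a primary label, alternative labels, synonyms, a source resource and
external codes. Edges carry predicates. Two predicate families matter:

* **Domain predicates** (disease–gene associations, treatments, phenotype
  links, …), which carry the biology.
* **Equivalence predicates** — `N_Name` (same concept name), `I_CODE`
  (shared external reference), and ontology-adopted `R_equivalentClass` and
  `R_exactMatch` — which link records of the *same* concept contributed by
  different source resources.

Parallel edges between a node pair are allowed when their predicates
differ; self-loops are rejected on input. Most of the analysis runs on the
*undirected simple view* (one unweighted adjacency per connected pair):
equivalence edges are semantically symmetric, and a mixed-predicate
knowledge graph gives no principled direction to hop counts or community
structure. PageRank is the one deliberately direction-aware measure.

## Stage 1: profile-network extraction

Given a seed cluster of related diseases, the profile network is the union
of the radius-3 ego graphs centered on each seed. Two design points were
genuinely open:

* **Traversal direction.** Default traversal ignores edge direction
  (`mode = "all"`); `out`/`in` modes exist for sensitivity analyses, since
  a direction-respecting extraction is defensible when predicates encode
  asymmetric relations.
* **Union semantics.** The node set is the union of the per-seed ego node
  sets, and the edge set is the *induced* edge set of the input graph on
  that union — not the union of per-ego edge sets. At a radius boundary the
  two differ: two frontier nodes reached by different seeds may be adjacent
  in the graph, and the induced convention keeps that edge. We chose the
  induced convention so the profile network is always an induced subgraph
  of the knowledge graph, which makes downstream counts (contraction
  conservation, community scores) exact statements about the parent graph.

Seeds missing from the graph are skipped with a warning that counts them;
extraction fails only when no seed resolves. The radius default of 3
reflects the typical reach of disease → gene → drug → related-concept
chains; radius is monotone (a larger radius never shrinks the network),
which the tests check as a property.

## Stage 2: contraction of equivalence components

Cross-resource redundancy is removed by contracting each connected
component (size ≥ 2) of the equivalence-edge subgraph into one merged node:

1. member attributes are concatenated (labels, synonyms, codes, resources);
2. edges internal to a component are deleted;
3. edges between a member and an outside node are reattached to the merged
   node, collapsing resulting parallel edges that share a predicate while
   keeping parallel edges with distinct predicates.

Merging is *transitive*: if A≡B and B≡C, all three merge, because
components — not edges — define merge units. Transitivity is what makes
contraction idempotent (a second pass finds nothing), a property the test
suite asserts on every synthetic graph it generates. Merged node identity
is deterministic: the lexicographically smallest member ID prefixed
`merged:`. A merged node's category is the *set* of member categories, since
disease/gene/drug bundles are exactly the interesting merges.

Label lists of merged nodes are synonym-filtered: scanning labels in
first-seen order, a label recorded as a synonym of an already-retained label
is dropped. The index is built from the members' own `synonyms` fields; no
external synonym resources are queried. Reattachment (rule 3) can create
adjacencies between concepts that were never directly linked — a drug
merged into a disease bundle inherits the bundle's gene edges. This is
inherent to contraction; the merge report (`merge_report()`,
`write_merge_report()`) retains full member provenance so such inferred
adjacencies can be audited rather than silently trusted.

Contraction obeys an exact conservation law — nodes after equals nodes
before minus Σ(component size − 1) — and never disconnects previously
connected nodes; both are tested on 50 generated graphs per run.

## Stage 3: modularity classes and their scores

The contracted network is partitioned by Louvain modularity maximization on
the undirected simple view at resolution γ (default 1.0). Two
reproducibility choices:

* The local-move order is randomized, but under a caller-supplied seed, so
  a run is exactly repeatable; `partition_stability()` reports the mean
  pairwise Rand index over replicate seeds for users who want to know how
  much the classes depend on that order.
* Community indices are renumbered contiguously from 0 in order of first
  appearance, so downstream artifacts are stable.

Each community is scored with `L_c/m − γ(k_c/2m)²` (internal edges,
member degree sum, total edges, resolution). The score rewards communities
that are dense inside relative to their total degree — the hub-rich
classes worth mining. At γ = 1 the scores sum to the partition's Newman
modularity Q, which the tests verify against both a from-scratch
implementation of Q and igraph's, on random partitions of random graphs.
Communities with three or fewer nodes are dropped before ranking: below
four nodes the five centrality measures are degenerate (in a triangle every
node is every centrality's argmax). Ties in the ranking break by community
index ascending.

## Stage 4: centralities and the TNCS

Five measures are computed per node *within its community subgraph* —
influence is assessed relative to a node's own modularity class, not the
whole profile network:

| measure | view | convention | default parameters |
|---|---|---|---|
| degree | undirected | raw adjacency count, unnormalized | — |
| closeness | undirected | Wasserman–Faust component-scaled, in [0, 1] | — |
| betweenness | undirected | Brandes counts / ((n−1)(n−2)/2), in [0, 1] | — |
| eigenvector | undirected | power iteration, max-normalized to [0, 1] | 100 sweeps |
| PageRank | directed | damped iteration, sums to 1 | damping 0.85, L1 epsilon 0.001 |

Numerical choices worth knowing:

* **Eigenvector centrality** iterates the unit-shifted matrix A + I rather
  than A. On bipartite structures (stars, paths, trees) the unshifted
  iteration oscillates between the two node classes and a fixed sweep count
  lands on an arbitrary phase; the shift leaves the principal eigenvector
  unchanged while guaranteeing convergence on every connected graph. The
  sweep count (100) is exposed; on the test fixtures the node ordering is
  identical for 50 and 200 sweeps.
* **Closeness on disconnected community subgraphs** uses the
  Wasserman–Faust form `((r−1)/(n−1)) · ((r−1)/Σd)` with `r` the node's
  component size, keeping scores in [0, 1]; isolated nodes score 0.
* **PageRank** redistributes dangling mass uniformly and stops when the L1
  change of a sweep drops below epsilon; with epsilon = 0.001 the result
  agrees with the exact linear-system fixed point to about 1e−2, which is
  far below the gaps that decide top-5 membership in practice.
* An **edgeless community** has no defined eigenvector centrality and is an
  error; it cannot arise from Louvain classes of four or more nodes.

For each measure the top five nodes are selected (ties by node ID), their
raw scores min–max normalized to [0, 1], and each node's TNCS is the sum of
its five normalized scores — range [0, 5], with 5 attained exactly by a
node that is the argmax of every measure. Two normalization scopes are
implemented because the procedure can be read either way: `top5_union`
(default) normalizes within each measure's top-5 list and credits 0 for
measures where a node is outside the top 5; `community_all` normalizes over
the whole community. Both are reported by name in every artifact, and on
hub-dominated fixtures they agree on the winner. When a measure's top-5
values are all equal, min–max normalization is degenerate; we map the
values to 0 rather than 0.5 or 1, keeping TNCS a conservative lower bound
(a measure that cannot distinguish nodes should not credit them).

## The synthetic generator

`generate_kg()` emulates the features of a multi-resource knowledge graph
that this pipeline actually exercises, at desk scale:

* ~200 concepts by default (80 diseases, 70 genes, 30 drugs, 20
  phenotypes) across 3 source resources;
* planted-partition domain edges over 4 communities with `p_in = 0.3`,
  `p_out = 0.01` — well-separated but not trivially so;
* one planted hub per community wired to all of its members (the known
  right answer for candidate ranking);
* each concept duplicated under an extra resource with probability 0.15 and
  linked to its original by one uniformly-chosen equivalence predicate; a
  duplicate's primary label is one of the original's synonyms and it
  carries a spurious alternative label, so contraction and synonym
  filtering both have real work;
* a seed cluster of 10 diseases drawn preferentially from one community.

Edge probabilities and the duplication rate were fixed once at values that
give a sparse (density ≈ 0.04), clearly modular graph of the kind
community detection is expected to resolve. All draws come from one RNG
stream seeded per call; the caller's RNG state is untouched.

What the generator does **not** emulate: the heavy-tailed degree
distribution of real knowledge graphs (planted-partition edges are
near-Poisson within blocks), equivalence components larger than two,
million-node scale, or predicate semantics beyond category pairs.
Consequently, passing the planted-recovery tests shows the pipeline is
*correct* — it recovers structure that is genuinely there — but says
nothing about how informative TNCS rankings are on a particular real graph,
where community separation is weaker and hubs are less clean.

## Validation design and problem sizes

The test suite validates every stage against independent oracles written
directly on adjacency matrices: BFS for distances and ego sets, dynamic
programming path counts for betweenness, dense eigendecomposition for
eigenvector centrality, an exact linear solve for PageRank, and a
from-scratch modularity formula. Centralities are checked exhaustively on
every connected graph of 2–7 nodes (the graph atlas), plus sampled
connected 8-node and 30-node graphs; modularity-score sums on 100 random
partitioned graphs; contraction laws on 50 generated graphs; and planted
community/hub recovery on 20 generated 200-concept graphs (adjusted Rand
index against ground truth, and the fraction of ranked communities whose
top-TNCS candidate is the planted hub). These sizes keep a full run around
two minutes while the exhaustive tier still covers every small-graph corner
case.

## Known limitations

* Contraction is fully rule-based; a production knowledge graph may contain
  equivalence edges that a curator would veto, and such merges propagate
  into candidate descriptions. The merge report is the audit surface.
* Louvain output depends on the move order even when seeded; only the seed
  makes it reproducible, not canonical. Resolution is exposed but the
  small-community filter (> 3 nodes) assumes γ near 1.
* TNCS aggregates five correlated measures with equal weight; it is a
  ranking heuristic, not a probability, and offers no uncertainty.
* Candidate ranking stops at structure: no literature or clinical evidence
  is consulted, which is deliberate — the output is a hypothesis list.
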