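---
title: "Explaining multi-omics changes with weighted influence paths"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Explaining multi-omics changes with weighted influence paths}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metregr)
```

## The problem and the model

An omics experiment perturbs a cell (a knockout, a nutrient shift) and
observes changes (transcripts, proteins, metabolites). `metregr` searches a
combined metabolic + regulatory network for *mechanistic routes* between the
perturbed (condition) and changed (effect) entities. The central modelling
commitments are:

* **Logical entities.** A gene, its protein product, and homomultimers of
  that product rise and fall together for the purposes of influence
  propagation, so they are collapsed to one node (canonical id: gene over
  monomer over complex, then lexicographic — a deterministic, gene-centric
  naming). Chemically modified forms (a phosphorylated protein) and
  heteromultimeric complexes have their own causal state and stay separate.
  The coalescing needs a gene→product link, which the schema carries as an
  optional `gene` field on protein entities.
* **Influence edges with specificity costs.** Edges point from the
  influenced entity to its influencer, the direction in which the graph is
  grown outward from the effects. Most prices are `1 + penalty` (producing
  side, regulators) or `2 + penalty` (consuming side, biasing the search
  toward upstream explanations); the penalty grows with how many reactions
  or genes the entities touch, divided by 10 or 20. This is a deliberately
  blunt heuristic: weighting by promiscuity is known to make lightest-weight
  metabolic routes more biologically meaningful than hop-count shortest
  paths, at the accepted risk of missing true routes through hubs like
  pyruvate or Crp.
* **Input-entity override.** An edge to any user-supplied entity costs a
  flat 0.1, biasing routes toward the entities of interest.
* **Ubiquity is data.** Whether a compound is excluded from substrate edges
  is a per-entity flag; when absent, a default name list (water, ATP, ADP,
  AMP, phosphate, diphosphate, H+, NAD(H), NADP(H), CO2, O2) is applied.
  The list is an overridable stand-in — no canonical enumeration exists, so
  it must remain user data.

## Parameters

| parameter | default | units | why |
|---|---|---|---|
| `C_max` | 20 | path cost | growth cutoff; roughly an upper bound on unit-cost steps between condition and effect |
| `offset` | 2 | path cost | admits paths about two unit steps dearer than the per-pair minimum, since the cheapest path is not always the most plausible |
| `max_paths` | 25 | count | per-pair display budget; beyond it, parity filtering then offset halving |
| penalty multiplier | 1.5 | × `C_max` | per-unreached-target penalty in the undirected influence score, so broad influencers outrank narrow ones |
| sign policy | table | — | mass-action defaults (production +, consumption −, inhibition −); replaceable because only regulation records carry authoritative signs |

`C_max` and the 1.5 multiplier are fixed by the method definition; `offset`
and `max_paths` are display-budget choices exposed as configuration.

## Algorithmic and numerical choices

* **Graph growth** is best-first with a priority queue ordered by `(cost,
  node id)` — the id tie-break makes results independent of hash order.
  Node *creation* requires `C_N + edge < C_max`; edges between existing
  nodes are always recorded. Per-root path costs are updated as
  `PC[root, N'] = PC[root, N] + edge` (the update is read source-side, the
  only reading consistent with the accompanying minimisation) and improved
  entries are propagated recursively along stored edges with a
  strict-improvement guard, which terminates on cycles. A node whose
  minimum cost drops is re-inserted into the queue; with near-zero edge
  weights (0, 0.1) this restores exact shortest-path semantics, verified in
  the test suite against an independent Bellman-Ford fixpoint oracle. The
  cutoff is interpreted purely as *cost*, never hop depth.
* **Transcription units** are dead-end pseudo-nodes: they acquire path
  costs (so two genes sharing an operon meet at a cost-0 explanation in
  undirected mode) but are never expanded, and their edges stay at cost 0
  even for input entities — lifting them to 0.1 would make operon links
  *worse* than other input links for no reason.
* **Transporter edges** require the influenced species to be among the
  reaction's transported substrates; other substrates of a transport
  reaction see ordinary enzyme edges. `|R_I=transporter|` counts transport
  reactions catalysed by `I`, symmetric with the enzyme count.
* **Reversible reactions** license both the producing and consuming reading
  of every substrate role (distinct provenance per direction) and force the
  sign to ambiguous, since such reactions can support either parity.
* **Path enumeration** is depth-first over simple paths (repeated nodes
  cannot lower cost under non-negative weights and clutter diagrams),
  pruned with exact remaining-distance bounds from a reverse shortest-path
  pass — admissible, so enumeration is complete within the bound (verified
  against exhaustive search). Cost comparisons use a 1e-9 slack so
  floating-point noise never drops a boundary path. Ties in path order are
  broken by edge-id strings.
* **Influence scoring** reads "minimum path length" as minimum path *cost*:
  the graph stores costs and hop counts appear nowhere in the method. Only
  nodes reaching ≥ 2 targets are scored; targets absent from a node's
  path-cost map are penalised rather than treated as undefined. Ranking
  ties break by breadth (more targets first), then id.
* **Reduction order** when a pair exceeds `max_paths`: parity filter first
  (it uses information, the offset only cost), then halve the offset toward
  0, finally truncate to the cheapest survivors.
* **Phase-3 partition**: a node that is both reaction-associated and
  regulated (an enzyme under transcriptional control) goes to the metabolic
  group, matching the group definition; its regulatory edges survive as
  inter-component links. Lacking curated main-compound annotations,
  "primary" substrates are those present in the filtered graph, plus — for
  a reaction side with no such member — the lexicographically first
  non-ubiquitous substrate, forced in so the reaction can be drawn;
  everything else (and every ubiquitous compound) is suppressed as a side
  metabolite. Layout is delegated to the DOT renderer with components as
  clusters; no attempt is made to reproduce a proprietary pathway layout.

Degenerate inputs are handled explicitly: empty networks validate; an
effect with no influencers yields a one-node graph; a condition absent from
the influence graph is a reported unconnected entity, not an error; fewer
than two undirected targets is an error, as the mode is undefined.

## What the synthetic generator emulates — and what it does not

`generate_network()` produces validated networks with heavy-tailed
metabolite participation (so hub compounds exist and the specificity
weighting is genuinely exercised), signed transcriptional regulation,
translational/sigma/modulation/cofactor records, transport and
protein-binding reactions, homo- and heteromultimers, a modified form and
transcription units; the default sizes (12 metabolites, 10 reactions, 6
enzymes, 3 TFs) give graphs of a few dozen logical nodes. It does **not**
mimic the scale, degree correlations or curation biases of a real
pathway/genome database, so green tests demonstrate algorithmic
correctness — cost semantics, enumeration completeness, cover properties —
not biological plausibility of routes in any real organism.
`planted_path_network()` buries one known route of chosen edge types under
decoy structure that never touches the condition entity; recovery of the
planted route checks the end-to-end pipeline rather than path-ranking
quality against biology.

The test suite sizes are deliberate: shortest-path oracles run on ten
seeded networks of at most 60 logical nodes, enumeration oracles on twenty
networks small enough for exhaustive search, recovery on one hundred
planted instances at twenty decoys — large enough to exercise every code
path, small enough that the whole suite runs in about a minute.

## Worked sketch

```{r example}
net <- toy_network()
g1 <- build_metreg_graph("M0", net, input_entities = c("M0", "TF0"))
tidy(g1)
g2 <- filter_directed(g1, "TF0")
cat(path_report(g2), sep = "\n")
g3 <- build_explanation_graph(g2, net,
                              target_spec(c("M0", "TF0"),
                                          c("effect", "condition")))
glance(g3)
```

## Known limitations

* No kinetics, stoichiometry or flux: edge costs are structural heuristics,
  and the authors of such weighting schemes expect them to be tunable.
* No compartments beyond the transport flag, and no import of
  BioCyc/Pathway Tools native formats or SBML (future work).
* Undirected mode's covering set is intentionally not minimal: it keeps
  better-scoring influencers even when coverage becomes redundant.
* Sign defaults for reaction-derived edges are mass-action intuition, not
  data; supply a sign-policy override where regulation signs matter.
* Explanation output is a static styled graph; there is no interactive
  display.
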