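# metregr

`metregr` explains multi-omics results mechanistically. Given a combined
metabolic and transcriptional-regulatory network and small sets of
**condition** entities (genes, proteins or metabolites deliberately perturbed
in an experiment) and **effect** entities (those observed to change), it
searches the network for weighted paths of influence linking them, ranks
candidate common influencers, and emits an annotated explanation graph that a
biologist can read as a set of hypothesised routes of action.

It is aimed at systems-biology analyses where a differential-expression or
metabolomics hit list is in hand and the question is *"by what mechanism
could the perturbation have produced these changes?"*.

## The method

The pipeline has three phases:

1. **Influence-graph construction.** An influence graph `G1` is grown
   outward from the effect entities with a best-first (Dijkstra-style)
   search. Nodes are *logical entities*: a gene, its product, and any
   homomultimers of the product are one node; chemically modified forms and
   heteromultimeric complexes are distinct nodes. Edges run from an
   influenced entity `X` to each influencer `I` licensed by the network
   (reactants/products/enzymes/transporters of reactions involving `X`;
   transcriptional, translational, sigma-factor, modulation and cofactor
   regulators; complex components; and, in undirected mode, cost-free
   transcription-unit links). Each edge is priced by a *specificity
   weighting*, e.g.

   * reactant of a reaction producing `X`: `1 + (|R_X=sub| + |R_I=sub|)/20`
   * enzyme of a reaction consuming `X`: `2 + |R_I=enz|/20`
   * transcriptional regulator: `1 + (|Regs_X| + |G_I=reg|)/20`

   where `|R_X=sub|` counts the other reactions in which `X` is a substrate,
   and so on — so lightest paths avoid hub metabolites and global
   regulators. Influencers that are themselves input entities cost a flat
   `0.1`; ubiquitous compounds (water, ATP, ...) never generate substrate
   edges. Growth stops at a maximum path cost `C_max` (default 20). Each
   node stores its minimum cost `C` to any root and a path cost `PC` per
   root.

2. **Filtering.** In *directed* mode every (effect, condition) pair is
   connected by enumerating all simple paths within an `offset` (default 2)
   of the pair's minimum cost; overlarge path sets are reduced by parity
   filtering (when directions of change are given) and offset halving. In
   *undirected* mode (effects only), every node reaching two or more targets
   receives an influence score `sum(PC to reached targets) + 1.5 * C_max *
   (#unreached targets)`; a greedy covering set of the best-scoring
   influencers is then posited as the condition set and the directed
   machinery reused. Each path carries a parity — the product of its edge
   signs, with reversible-reaction edges ambiguous — checked against the
   observed up/down directions.

3. **Explanation graph.** The filtered graph is partitioned into metabolic
   and regulatory connected components; metabolic components are assembled
   into temporary pathways (forcing in primary substrates needed to draw
   each reaction, suppressing side metabolites and enzymes outside the
   graph), styles are assigned (arrowheads by influence type, colours by
   sign and direction of change), and the result is exported as DOT,
   GraphML or JSON.

## Worked example

The bundled fixture network contains a five-reaction pathway and a small
transcription-factor cascade in which TF0 represses TF1, which activates
expression of the enzyme E1 catalysing M0 → M1:

```r
library(metregr)
net <- toy_network()
res <- run_explain(net,
                   target_spec(c("M0", "TF0"), c("effect", "condition"),
                               c("down", "up")),
                   mode = "directed", out_dir = "results")
cat(path_report(res$g2), sep = "\n")
#> == M0 -> TF0 (2 paths) ==
#>   cost 3.250 parity + [inconsistent]: M0 -[enzyme-of-consuming,-]-> E1 -[transcriptional-regulator,+]-> TF1 -[transcriptional-regulator,-]-> TF0
#>   cost 4.350 parity ambiguous [consistent]: M0 -[product-of-consuming,ambiguous]-> M1 -[enzyme-of-producing,+]-> E1 -[transcriptional-regulator,+]-> TF1 -[transcriptional-regulator,-]-> TF0
```

Reading the first path in the direction influence acts: TF0 represses TF1,
TF1 activates E1, and E1 consumes M0 — a net positive chain
(− × + × − read backwards), which cannot explain TF0 *up* with M0 *down*,
so it is flagged inconsistent. The second route runs through the reaction
product M1 and contains an ambiguous step, so it can support either parity.
The costs are sums of the edge prices above (e.g. 3.250 = 2.05 + 1.10 +
0.10, the final step being cheap because TF0 is an input entity).

`res$g3` is the styled explanation graph (here one metabolic and one
regulatory component, five nodes); `run_explain()` writes it as
`results/explanation.dot` along with `paths.txt`, `unconnected.txt` and a
run manifest. In undirected mode an influencer ranking is produced instead:

```r
gu <- build_metreg_graph(c("E1", "E5", "TF2"), net, mode = "undirected")
score_influencers(gu)
#> # A tibble: 1 × 5
#>   entity score n_reached reached   per_target_cost
#> 1 TF0      4.7         3 <chr [3]> <dbl [3]>
```

TF0 reaches all three query genes (score = 2.3 + 1.2 + 1.2 with no penalty
term), so it is the covering influencer proposed to explain their
correlation.

A command-line front end with `explain`, `generate`, `validate` and
`export` subcommands ships in `inst/cli/metregr.R`, and
`generate_network()` / `planted_path_network()` provide seeded synthetic
networks for benchmarking every stage without a curated database.

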