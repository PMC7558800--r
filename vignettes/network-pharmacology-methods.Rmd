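---
title: "Methods: ADME screening, PPI module detection, and over-representation analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ADME screening, PPI module detection, and over-representation analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netpharm)
```

# The analysis

Network pharmacology asks how a multi-component preparation — here a
multi-herb formula — acts on a disease through many weak, overlapping
protein interactions rather than a single high-affinity target. The
standard desk workflow has five stages, and `netpharm` implements each as
an explicit, tested function:

1. **ADME screen** (`screen_compounds`): keep candidate compounds that are
   plausibly orally absorbable and drug-like.
2. **Target space** (`assemble_target_sets`, `filter_disease_genes`,
   `classify_nodes`): collapse compound–target mappings into per-herb and
   union gene sets, filter disease genes by relevance, and classify every
   gene as shared, drug-only, or disease-only.
3. **Interaction network** (`read_string_tsv`, `build_network`,
   `degree_table`): build an undirected, categorized protein–protein
   interaction (PPI) graph and rank hubs by degree.
4. **Module detection** (`find_modules`): locate densely interacting
   regions with a from-scratch MCODE implementation.
5. **Enrichment** (`enrich`): test gene sets for over-represented
   annotations with hypergeometric or EASE statistics, BH correction, and
   fold enrichment.

`run_pipeline` chains the stages and writes the report bundle; the
synthetic-data module generates all five input dialects with planted
ground truth, so the entire chain is verifiable offline.

# Stage models and parameters

## ADME screening

A compound passes when all three hold: oral bioavailability
$\mathrm{OB} \ge 30\%$, Caco-2 permeability $> -0.4$ (log scale), and
drug-likeness $\mathrm{DL} \ge 0.18$. The operators are deliberately
asymmetric — the OB and DL bounds are inclusive, the Caco-2 bound strict —
because that is how the rule is conventionally stated, and the package
treats boundary behaviour as part of the contract (a compound at Caco-2
exactly $-0.4$ fails). Compounds flagged as literature-supported bypass
the screen entirely but remain marked `whitelisted` in every output, so
their provenance is never laundered into the screened set. A non-whitelist
record with any missing property is rejected with reason
`missing_property`; silent passes on incomplete data are not possible.
Identity is by `compound_id`; duplicate ids are an input error rather than
a silent merge, since compound name synonymy is common and ids are the
only stable key.

## Target space

Gene symbols are normalized by trimming and uppercasing only. Alias
resolution is out of scope: it would drag in a mutable external table and
make results irreproducible across its versions. Disease genes keep the
maximum relevance when a symbol repeats (database exports commonly repeat
symbols), and the relevance filter is strict (`> 2.5`), so a gene at
exactly the threshold is excluded. The three-way classification
(`shared` = targeted disease genes, `drug_only`, `disease_only`) is a
partition; its counts are the Venn numbers reported alongside published
networks of this kind.

## Interaction network

The reader accepts the tab-separated export dialect of STRING-style
databases: two node columns and a combined-score column, names
configurable. Reciprocal duplicate rows collapse keeping the maximum
score; self-loops are dropped; scores below `score_min` (default 0.4,
the usual "medium confidence" level, given on the 0–1 scale) are removed.
Both score dialects — probabilities in $[0,1]$ and integers in 0–999 —
are accepted; by default the dialect is inferred from the maximum
observed value (anything above 1.5 implies the integer dialect), and an
explicit `scale` argument overrides the inference for pathological files.
Scores are stored as found in the file.

With `restrict = TRUE` (default) the network is the categorized gene
space: edges touching an uncategorized symbol are dropped, and
categorized genes with no surviving edge are kept as isolated nodes.
Whether a published network of this kind includes interactions among
disease genes not touched by any compound target is usually ambiguous;
`restrict` covers both readings. Hubs are ranked by degree only — degree
is the criterion this workflow actually uses — with lexicographic
tie-breaking so the table is a total order and reruns are
byte-identical.

## MCODE module detection

The detector is implemented from first principles on adjacency lists.

**Vertex weighting.** For node $v$, let $H$ be the subgraph induced on
the closed neighborhood $N[v]$, $k$ the highest core number in $H$, and
$C$ the $k$-core of $H$. The weight is $w(v) = k \cdot \mathrm{density}(C)$
with loop-free density $2E/(N(N-1))$. Nodes below the degree cutoff
(default 2) get weight 0. Core numbers come from iterative
minimum-degree peeling, written here and cross-checked in the tests
against an independent implementation.

**Seed and grow.** The highest-weight unvisited node seeds a complex,
which grows breadth-first to `max_depth`: an unvisited neighbor is
admitted when its weight is at least $(1 - c)$ times the weight of the
node being expanded, with node score cutoff $c = 0.2$ by default.
Published descriptions of this step are ambiguous about whether the
comparison is against the seed's weight or the expanding node's weight.
This package thresholds against the expanding node, a deliberate design
choice: in graphs whose dense regions are stochastic (edge probability
well below 1) the weights inside a module disperse by far more than 20%,
and an outlier seed freezes a seed-relative threshold so high that the
complex fragments — on planted-partition benchmarks the seed-relative
rule recovers essentially nothing, while the gradient-following rule
recovers the planted module (the property the package's recovery tests
assert). Descending a weight gradient still refuses steps into the
sparse background, because background weights sit far below module
weights.

**Post-processing.** A candidate is discarded unless it contains a
2-core. Haircut (default on) iteratively removes members with fewer than
two in-complex neighbors — exactly the 2-core of the candidate's induced
subgraph, and tested as such against brute-force pruning. If pruning
disconnects a candidate, the component containing the seed is kept (the
largest component, first member name breaking ties, if the seed itself
was pruned), preserving the invariant that a reported module is
connected. Fluff (default off) adds boundary nodes whose
closed-neighborhood density exceeds `fluff_threshold`; fluffed nodes may
repeat across modules and are excluded from the core-membership
disjointness guarantee.

**Scoring.** A module with $N$ nodes and $E$ induced edges scores
$\mathrm{density} \times N = 2E/(N-1)$. Report tables round to 3
decimals, the conventional presentation. All tie-breaks — seed order,
admission order, output order (score, then size, then seed symbol) — are
lexicographic, making the full output a deterministic function of graph
and parameters.

## Over-representation analysis

For a universe of $N$ genes, a term of $K$, and a query of $n$ (both
counted within the universe), the p-value of an overlap $k$ is the
hypergeometric upper tail

$$p = \sum_{i=k}^{\min(n,K)} \frac{\binom{K}{i}\binom{N-K}{n-i}}{\binom{N}{n}}.$$

The EASE variant recomputes the tail with $k-1$ (floored at 0) — a
conservative jackknife-style penalty that hits small overlaps hardest.
Both are always reported; `method` selects which drives the correction
and ranking. The default is the plain hypergeometric because it is
exactly verifiable against enumeration; EASE is provided because
DAVID-style tools default to it. False-discovery control is
Benjamini–Hochberg across the terms tested within one collection, never
pooled across collections. Fold enrichment is $(k/n)/(K/N)$. Results are
ranked by ascending p, ties by overlap count descending, then term id —
the "degree of enrichment, then count" convention.

The default universe is the union of the collection's term members: it
is the only background derivable from the collection itself. The
alternative (`universe = "network"`) counts against all categorized
network genes, which is more conservative when the collection annotates
only part of the network. Query genes outside the universe are dropped
and counted, never silently.

# The synthetic-data generator

The generator emulates the statistical structure each stage assumes,
with truth labels that no analysis stage reads:

- **Compound tables** draw pass/fail status per compound
  (probability `frac_pass`) and then sample properties just inside or
  just outside each bound, so screens exercise the thresholds rather
  than comfortable interior values.
- **Interactomes** follow a planted-partition model: within-block edge
  probability `p_in`, background probability `p_out`. This is the
  simplest model with the dense-region structure MCODE assumes.
  Deliberately, it is *not* degree-corrected: real interactomes have
  heavy-tailed degrees and literature bias that this generator does not
  mimic, so passing recovery tests demonstrates correctness of the
  algorithm on its own assumption, not performance on real networks.
  Edge scores are drawn on $[0.4, 0.99]$ so the default score filter is
  exercised without emptying the graph.
- **Annotation collections** contain random terms plus one designated
  term seeded with a chosen overlap into the first planted block —
  over-represented by construction when the overlap is large, and
  indistinguishable from chance when it is near $K n / N$.

All randomness flows from one integer seed through fixed per-table
offsets; the same spec reproduces byte-identical files. Mapping tables
and disease scores are generated so that every interactome gene is
categorized, which keeps the planted block intact through the
`restrict = TRUE` network stage.

# Numerical and design notes

- Degenerate inputs: empty networks yield empty module lists; singleton
  or empty member sets are errors for `module_score`; an empty disease
  set aborts the pipeline at `target_space` with a stage-named error.
- The traversal depth limit (`max_depth = 100`) exists for parity with
  the published parameter set; at desk scale it is never binding.
- Scores, p-values and weights are compared in tests at tolerances of
  1e-9 or tighter; report rounding (3 decimals) happens only at the
  presentation layer.
- Test and benchmark problem sizes are chosen for thorough coverage at
  interactive speed: exhaustive small-graph enumeration up to 5 nodes
  (1,106 labeled graphs) plus seeded 6–7-node samples for the haircut
  oracle; 100 seeded graphs up to 25 nodes for core numbers; 20
  replicates of 220-node planted-partition graphs for module recovery;
  the full $\binom{20}{5} = 15{,}504$ enumeration for the
  hypergeometric oracle.

# Limitations

- No alias/ortholog resolution; symbol normalization is lexical only.
- Degree is the only centrality; no betweenness or closeness.
- Module detection is unweighted; edge confidence scores filter the
  network but do not weight the density computation.
- Enrichment has no term-graph topology, ancestry propagation, or
  redundancy trimming.
- The planted-partition generator does not mimic real interactome
  degree distributions; conclusions about real-data performance require
  real networks.
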