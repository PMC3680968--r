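---
title: "Methods: overlap between SBML molecular interaction maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: overlap between SBML molecular interaction maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mapoverlap)
```

## The problem

Curated molecular interaction maps — metabolic, signalling or regulatory
pathways — are published as SBML documents: species (molecules, complexes,
genes) placed in compartments, connected by reactions with reactants,
products, modifiers and a reversibility flag. Two maps curated
independently rarely agree node-for-node, so asking "how much of map A is
contained in map B" needs approximate subgraph matching that tolerates
gaps (a species present in one chain but not the other) and mismatches,
while still respecting the biology: a species should map to a single
partner species, a compartment to a single partner compartment, and a
stretch of reactions to a single partner stretch.

`mapoverlap` computes such an overlap directly on the SBML graph topology,
with no intermediate format conversion, and scores it per reaction.

## Graph model

Each document becomes a labelled multidigraph. A reaction with reactant
set $R(r)$ and product set $P(r)$ is spliced into $|R(r)|\cdot|P(r)|$
directed edges, each labelled $r$; a reversible reaction contributes the
reversed edges too, carrying a reversed-orientation flag. Modifiers
$M(r)$ are edge attributes, never traversed; compartments are vertex
attributes. Incomplete reactions (empty reactant or product set) and
species appearing in no retained reaction are ignored. A species that
occurs only as a modifier is therefore not a traversal vertex, but its
reaction record keeps it so it can be mapped and scored.

## The comparison procedure

**Simple paths.** For every ordered species pair $(u, v)$ the package
enumerates all chains of *distinct* reaction ids of length at most $N$
(length is counted in reactions), and keeps only the chains of minimal
length for that pair. A pair may own several minimal chains, and $u = v$
(a cycle path) is allowed; cycle chains compete only against other chains
of the same pair. Intermediate species may repeat along a chain — only
reaction ids may not — and the interior species are recorded, because the
matching rules need them. Enumeration is a breadth-first frontier
expansion per source vertex; minimality falls out of the level order.

**Matching.** Two species are equivalent by default when their `name`
attributes are equal (exact, case-sensitive, after trimming surrounding
whitespace — the conservative reading of name equality); user-supplied
allow/forbid lists extend or restrict this, and species without a name can
only match through the allow list. Two simple paths match when start is
equivalent to start and end to end, unless:

* (a) the species pair or the chain pair is explicitly forbidden;
* (b) the two interiors contain an equivalent species pair — the shorter
  subpaths are then matchable on their own and carry the information at
  their own lengths;
* (c) the match breaks one-to-one structure at the pair level: a cycle
  path only matches a cycle path, and a path that stays within one
  compartment only matches a path that stays within one compartment.

Unequal chain lengths are precisely what makes the procedure gap- and
mismatch-tolerant: matched endpoints with unpaired interiors are gaps.
When every reaction in both chains is reversible and the forward
orientation fails, a reversed-orientation match (start with end) is
attempted, so a reversible chain can align against its mirror image. Each
(path, path) combination contributes at most one matched pair.

An explicitly *allowed* chain pair bypasses rule (b) only; endpoint
equivalence and rule (c) always apply. The allow list is not closed
transitively: each listed pair stands for itself.

**Consistency and clique search.** A set of matched path pairs is
consistent when its induced mappings are one-to-one on species, on
compartments and on reaction chains, where a chain and its reversed chain
count as one pathway and each reaction id may belong to at most one
matched chain per side. Pairwise compatibility under these rules defines
an undirected compatibility graph whose maximal cliques are the maximal
consistent sets. Cliques are enumerated with the pivoting Bron–Kerbosch
algorithm (Tomita pivot: the vertex of $P \cup X$ with most neighbours in
$P$; candidates visited in fixed index order, so enumeration order is
deterministic).

Because clique enumeration is exponential in the worst case, the solver
is staged: at stage $i = 1, \dots, N$ only path pairs whose larger chain
length equals $i$ are candidates, each candidate must be compatible with
everything already accepted, and among the enumerated cliques of the
stage the best one — highest provisional score $S(G_1,E) + S(G_2,E)$
(modifiers mapped before scoring), ties broken by clique size, then by
lexicographic vertex order — is unioned into the solution. Short chains
are the safest similarities, so they anchor the solution before longer,
gappier matches are considered. The staged result is a lower bound on the
global optimum; tests verify it never exceeds the brute-force optimum on
small instances and attains it when the optimum uses only shortest-length
pairs.

Optional limits bound the search: a maximum number of cliques per stage
and/or a wall-clock budget, split equally across the $N$ stages; a stage
that exhausts its budget keeps its best-so-far and the solution is
flagged truncated.

**Modifier mapping.** After the chains are fixed, modifiers of matched
chain pairs are mapped greedily in sorted order: each doc1-side modifier
takes the first equivalent, still-unmapped doc2-side modifier, preserving
injectivity of the species map.

**Scoring.** With $R_1$ the reaction ids of $G_1$,

$$S(G_1, E) = \frac{\sum_{r \in R_1} w(r)}{|R_1|}, \qquad
w(r) = \frac{|R_E(r)| + |P_E(r)| + |M_E(r)|}{|R(r)| + |P(r)| + |M(r)|},$$

where the $\cdot_E$ sets are the participants whose species are mapped by
the solution; $w(r) = 0$ when $r$ belongs to no matched chain. The score
is in $[0,1]$, asymmetric ($S(G_2,E)$ normalises by $|R_2|$), and reads
as "how much of this map is contained in the other". Participants are
counted per category with set semantics, so a species acting as both
reactant and product counts once in each category. A participant counts
only if the species itself is mapped — as a path endpoint, through a
shorter matched path of its own, or as a mapped modifier; the unpaired
interior of a gap match does not count, since only mapped species are
contained in the solution.

## Parameters

| parameter | default | meaning |
|---|---|---|
| `N` | 3 | maximum chain length in reactions; 3 keeps paths local and the pair set small, and is the value used throughout the package's benchmark harness |
| `max_solutions` | unbounded | cliques enumerated per stage |
| `max_time` | unbounded | seconds for the whole staged search, split equally across stages |
| allow/forbid lists | empty | prior knowledge: orthologs that should match, homonyms that should not |

## The synthetic fixture generator

`generate_toy_pair()` builds two SBML documents sharing a planted core:
a component with identical topology and name attributes but distinct ids
and compartments, embedded alongside a document-unique component with
disjoint names. Topologies: linear chain, branched tree, cycle, or random
reactions with 1–2 reactants and products. Options plant reversible
reactions, per-reaction modifiers, and (for linear cores) gap species
inserted mid-chain on one side only, turning the planted match into a gap
match. Because the core is species-disjoint from the unique components,
the expected solution has closed form: with $k$ planted reactions the
scores are $k/|R_1|$ and, with $g$ gap insertions, $k/(|R_2|)$ where the
two halves of each split reaction each score $1/2$. Default sizes (6
reactions, up to 8 species per document) are deliberately desk-scale:
large enough to exercise gaps, branching, reversibility and staging,
small enough that brute-force oracles (exhaustive path enumeration,
exhaustive clique search over vertex subsets) remain feasible in tests.

What the generator does *not* emulate: the heavy-tailed degree
distributions of real curated pathways, promiscuous currency metabolites
(ATP, H2O) that inflate overlaps, shared-id namespaces across documents,
and annotation noise in name attributes. Passing tests therefore
demonstrate algorithmic correctness on known ground truth, not retrieval
quality on real databases; the benchmark harness accepts any directory of
SBML files for that purpose.

## Benchmark protocol

`run_benchmark()` runs a leave-one-out, all-versus-all comparison over a
directory of maps: each map queries all others, hits are ranked by the
query-side score $S(\text{query}, E)$, and — when the documents share a
reaction-id namespace — the fraction of the query's reaction ids present
in the target is the gold standard, with any positive fraction labelled
related. Per-query and pooled AUC are computed by pairwise concordance
(Mann–Whitney, ties at 1/2); with a single class the AUC is reported as
`NA` rather than invented.

## Numerical and design choices

* **Determinism.** Path, pair and clique orderings are lexicographically
  fixed; repeated runs with the same inputs and limits give identical
  solutions. Generator output is byte-identical for a given seed.
* **Edge collapsing.** Duplicate (source, target, reaction, orientation)
  edges arising from set semantics are collapsed; a species on both sides
  of one reaction yields a self-loop edge.
* **Reversible reactions** are materialised as explicit reversed-flag
  edges at build time, keeping enumeration a plain traversal; forward and
  reversed edges may mix within one chain as long as ids stay distinct.
* **SBML dialect.** Level 2 and 3 documents are accepted; only
  compartments, species, reactions, species references and the
  reversibility flag are read (absent flags default to reversible, the
  Level 2 default); kinetic laws, rules, events and extension packages
  are ignored. Validation is structural, not semantic.
* **Degenerate inputs.** Empty graphs yield empty path sets; an empty
  match set is a valid solution with score 0; a graph with no retained
  reactions has no defined score and errors explicitly. Maps whose
  species all lack names cannot match by default — by design, since the
  default equivalence is the name attribute.
* **Output convention.** Pruned documents keep matched reactions in full
  definition (unmatched participants included); the merged overlap
  document writes one reaction per matched chain pair, doc1-side ids,
  only matched participants, with compartments preserved from doc1.

## Known limitations

The staged heuristic can miss globally optimal solutions that require
skipping a short match in favour of a longer one. Path enumeration stores
all minimal chains per pair, which can grow quickly on dense maps —
bounded in practice by small `N`. Chain-level allow/forbid rules identify
pathways by exact ordered id tuples (or their reversals), so they do not
generalise across alternative chains. The AUC of the benchmark is
undefined (reported `NA`) when every pair is related or none is.

## Problem sizes used by the shipped checks

The test-suite oracle sweeps use 200 random multidigraphs of up to 8
species and 10 reactions with $N \le 4$ for path enumeration, and 200
random graphs of up to 12 vertices for clique enumeration — the largest
sizes at which the independent brute-force oracles are exact and fast.
The acceptance script reruns the pipeline on generated fixture pairs
(identity, strict subgraph, gap insertion) and a three-map benchmark
directory, reporting the scores and pooled AUC these constructions fix in
closed form.
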