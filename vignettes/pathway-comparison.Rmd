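---
title: "Comparing metabolic pathways by traversal alignment and edge differentiation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing metabolic pathways by traversal alignment and edge differentiation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathcomp)
```

## The problem

A metabolic pathway is an ordered series of enzyme-catalyzed reactions
turning substrate metabolites into products. Modeled as a directed graph
whose nodes are metabolite labels, comparing two pathways is a graph
alignment problem that is NP-complete in general. `pathcomp` implements
two deliberately cheap comparison methods meant as a screening step: a
2D-to-1D reduction followed by classical sequence alignment, and a direct
edge-set differentiation. This vignette explains the model behind each,
the parameters that matter, the numerical conventions, and what the
synthetic test corpus does and does not establish.

## Graph model and formats

A `pathway_graph` stores a pathway as a dictionary from node label to the
labels it directs to. Labels are unique within a graph and are compared by
exact, case-sensitive string equality everywhere — no normalization of
metabolite names is attempted, since labels function as identifiers.
Dictionary semantics merge duplicate edges; labels appearing only on the
successor side are materialized as nodes with no successors, so DPW files
that omit leaf keys load correctly (files in the wild come in both
dialects). Successor lists are kept sorted so that serialization and
traversal are deterministic. Self-loops are accepted and count one toward
complexity; a self-looped node is neither origin nor destiny. Family
membership — database-hierarchy categories a pathway belongs to — travels
in a JSON sidecar (`families.json`), since pathway files themselves carry
no such field.

The RNL dialect stores reactions as (substrates, products) label lists.
Conversion to a graph takes every substrate–product pair of a reaction as
one directed edge and deduplicates; reaction identifiers are dropped,
because both comparison methods identify a reaction purely by its source
and target metabolites.

## Traversal: from graph to sequence

An *origin* (out-degree ≥ 1, in-degree 0) models an initial substrate; a
*destiny* (in-degree ≥ 1, out-degree 0) an end product. An isolated node
is neither, by the literal degree definitions. A pair of pathways is a
comparison candidate when each graph has a valid *lecture*: an
origin–destiny pair where the destiny is reachable from the origin.
Reachability must be checked per pair — some destinies are only reachable
from one of several origins.

Traversal is breadth-first: nodes are visited by levels, which mirrors how
reactions proceed from substrate to product; depth-first traversal (also
provided, for comparison) tends to bury the end product in the middle of
the row. Three conventions are fixed here because the method itself does
not fix them:

* **Sibling order.** Children are enqueued in ascending label order.
  Deterministic output is required for reproducible scores; no ordering is
  otherwise canonical.
* **Stopping rule.** The traversal continues past the destiny until every
  reachable node is visited; the destiny is a validity requirement, not a
  terminator. A traversal has *full coverage* when it visits the whole
  graph, and restricting comparisons to full-coverage traversals is the
  "fair comparison" filter of the batch pipeline.
* **Cycles.** A visited set makes traversal cycle-safe. Generated test
  graphs are acyclic, but real exports may not be.

When both sides have several valid lectures, each combination is a
separate comparison. Label equality of the two origins (and of the two
destinies) is annotated on each candidate rather than required, so both
restricted and unrestricted analyses can be run downstream.

## Alignment scores

Tokens are whole metabolite labels; two tokens match iff their strings are
equal. All three aligners use linear (per-symbol) gap costs — the
absolute-score formula counts gaps individually, so affine penalties have
no place here:

$$S = x\,m + y\,n + z\,g$$

with match count $x$, mismatch count $y$, gap count $z$. Defaults are
$m = 1$, $n = -1$; the global aligner is always run at $g \in \{-2, -1,
0\}$, while local and semi-global alignment use $g = -2$. The headline
global score uses $g = 0$: a pathway lecture, unlike a sequencing read,
loses nothing at a gap, and negative gap costs only push scores down
without changing the ranking signal. Relative scores divide the match
count by the longer sequence (global) or the shorter one (local,
semi-global), so relative global is bounded by the size ratio of the
traversals — the "diagonal" visible when plotting scores against size
ratio — and the other two are bounded by 1.

Numerical conventions:

* **Canonical counts.** Several alignments can achieve the optimal score
  while differing in match count (at $g = 0$, a substitution column can
  equally be spelled as two gaps). The dynamic programs therefore optimize
  the lexicographic objective (score, then match count, then fewest gaps).
  All three components are additive and operand-symmetric, so the reported
  $x$, $y$, $z$ are canonical, invariant under swapping the sequences, and
  equal to the maximal match count among score-optimal alignments — which
  the exhaustive reference scorer (`align_enumerate`, a C++ path
  enumerator with no dynamic programming) recomputes independently in the
  tests.
* **Semi-global convention.** End gaps are free in *both* sequences
  ("overlap" alignment): the most symmetric standard reading, chosen
  because it preserves score symmetry. Free end gaps appear in the output
  rows but are excluded from $z$, keeping the absolute-score identity
  intact.
* **Tie-breaks.** Traceback prefers diagonal over consuming the first
  sequence over consuming the second; the local aligner reports the first
  optimal cell in row-major order, the semi-global aligner scans the last
  column then the last row. These affect only which optimal rows are
  shown, never the counts.
* **Degenerate inputs.** Empty sequences are rejected; the local empty
  alignment scores 0 with $x = y = z = 0$.

Two provable laws anchor the test suite: pathways sharing no label score
$x = 0$ and relative 0 in every mode (matches require equal labels), and
relative global never exceeds the traversal size ratio.

## Differentiation by Pairs

The edge-level method lists the reactions (`"node_0 -> node_1"` strings)
present in one graph and absent from the other, in both directions, and
summarizes them as (unique edges) / (sum of complexities) — a difference
fraction: 0 means identical edge sets, 1 disjoint ones. Because plotting
conventions differ, reports carry both the difference fraction and its
complement (`dbp_similarity`), clearly labeled. Parsing an edge string
splits on the last `" -> "`, tolerating the substring inside a source
label; graphs whose labels contain `" -> "` trigger a load-time warning
since their edge strings cannot be parsed back unambiguously. Two
edgeless graphs have no defined numerical score (division by zero) and
are rejected.

## Pair features and experiment planning

Three ratios characterize a pair: size ratio and complexity ratio
(smaller over larger node/edge count) and the equivalent-nodes ratio
(shared labels over the larger size). Complexity ratio is extended to
edgeless graphs — 1 when both are edgeless, 0 when exactly one is — to
keep it total. Factor bucketing follows the inequality directions of the
experimental design exactly: size ratio < 0.4 is `different`, [0.4, 0.7)
`medium`, ≥ 0.7 `similar`; common families 0 is `none`, 1–3 `few`, ≥ 4
`several`. Families are compared as *sets* (a pathway may belong to
several), and `families_annotated` distinguishes "annotated but disjoint"
from "no annotation recorded", which the count alone conflates.

`plan_doe()` plans a two-factor experiment: levels₁ × levels₂ × replicas
runs, drawing distinct pairs uniformly without replacement within each
factor cell under a caller-supplied seed, so every planned comparison is
unique. The canonical design is 3 × 3 × 50 = 450 runs.

## The synthetic generator

`generate_pathway()` emulates the curated corpus the method targets:
directed acyclic graphs of 2–20 nodes, one or more origins, at least one
destiny, every node reachable from some origin. Nodes are laid on a
topological backbone; each non-origin node receives one parent among its
predecessors, origins are forced to out-degree ≥ 1, and extra forward
edges add density without creating cycles. With a single origin every
node is reachable from it, so full-coverage traversals are guaranteed —
matching the corpus selection the batch defaults (sizes 2–20,
single-origin filter) mirror. `generate_pair()` controls the shared-label
count exactly (`round(overlap_fraction × max size)`), the family-set
intersection, and — with `ordered_overlap` — builds chain pairs whose
shared labels appear in matching order, the construction that attains the
size-ratio bound.

What the generator does *not* model: real metabolite nomenclature,
stoichiometry, reaction reversibility, cycles, or the label-frequency
structure of a real database (in MetaCyc-like corpora a few currency
metabolites recur in many pathways; here overlap is placed uniformly).
Passing tests therefore establish the algebraic and structural laws of the
method on realistic graph shapes, not distributional claims about any
particular database snapshot.

## Problem sizes used in the checks

The exhaustive-equivalence check runs the dynamic programs against the
enumeration oracle on *every* pair of sequences of lengths 1–5 over a
4-letter alphabet, reduced soundly to canonical first-occurrence
relabellings (scores depend only on the pattern of label equalities;
ordered pairs (m, n) follow from (n, m) by the symmetry law) — about
63,000 canonical pairs under five scheme/mode configurations. Property
sweeps use 500 seeded synthetic pairs of sizes 2–20; the zero-overlap law
is checked on 200 disjoint-label pairs through the full pipeline; the
size-bound search uses 1,000 random 3-vs-10 pairs. These sizes give full
coverage of the short-sequence space and stable property sampling while
keeping a complete test run in the low minutes on one core.

## Known limitations

* Breadth-first linearization loses 2D structure by design; two different
  graphs can share a traversal. The DbP view partially compensates, which
  is why reports always carry both.
* Relative scores compare traversals, not graphs: on multi-origin
  pathways, different lectures of the same pair can score differently,
  and all candidates are reported as separate rows (an optional
  best-per-pair reduction keeps the maximal relative global score).
* No substitution matrices or enzyme-aware edge comparison: a mismatch is
  a mismatch regardless of chemical similarity.
* The statistical analysis of batch output (ANOVA and its variants) is
  out of scope; the pipeline emits the tidy per-run CSV such tools
  consume.
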