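# pathcomp

Low-cost pairwise comparison of metabolic pathways represented as directed
graphs of metabolite labels.

Comparing metabolic pathways ("pathway alignment") is in general an
NP-complete graph problem. `pathcomp` implements two inexpensive
alternatives that work well as a screening step before deeper analysis:

1. **Traversal alignment.** Each pathway graph is linearized into a 1D
   sequence of metabolite labels by breadth-first traversal from an
   *origin* node (out-degree ≥ 1, in-degree 0 — an initial substrate)
   towards a *destiny* node (in-degree ≥ 1, out-degree 0 — an end
   product). The two sequences are then aligned with standard dynamic
   programming — global, local and semi-global — scoring each alignment
   with the linear absolute-score formula

   S = x·m + y·n + z·g

   where *x*, *y*, *z* count matches, mismatches and gaps and *m*, *n*,
   *g* are their values (base values: m = 1, n = −1; g ∈ {−2, −1, 0} for
   global, g = −2 for local and semi-global). Relative scores normalize
   the match count by sequence length:

   - relative global rG = x_G / max(|S|, |T|)
   - relative local rL = x_L / min(|S|, |T|)
   - relative semi-global rSg = x_Sg / min(|S|, |T|)

   A relative score of p is read as "at least p·100% of the smaller
   traversal is present, in analogous order, in the longer one". The
   relative global score is bounded above by the size ratio of the two
   traversals (the "diagonal"), and pathways sharing no metabolite always
   score 0 on every relative score.

2. **Differentiation by Pairs (DbP).** The graphs are compared directly at
   the reaction level: each edge is written as `"node_0 -> node_1"`, and
   the reactions unique to each pathway are listed. The numerical DbP
   score divides the number of unique reactions by the summed edge counts
   (complexities), giving a difference fraction in [0, 1] — 0 for
   identical edge sets, 1 for disjoint ones.

The package also provides: readers/writers for the two JSON pathway
dialects (DPW adjacency dictionaries and RNL reaction layouts, with
RNL→DPW conversion), candidate-selection rules (origin/destiny presence,
valid lecture, full coverage), pairwise structural features (size,
complexity and equivalent-nodes ratios, common families) with the
factor bucketing used for designed experiments, a 3×3×replicas experiment
planner, a seeded synthetic pathway generator, and a batch pipeline that
writes one CSV row per comparison. A thin command-line front end lives at
`inst/cli/pathcomp.R` (subcommands `compare`, `batch`, `convert`,
`features`, `plan-doe`, `synth`).

## Worked example

```r
library(pathcomp)

fx <- fixture_suite()           # canonical toy graphs
print(fx$chain3)
#> <pathway_graph> chain3: 3 nodes, 2 edges
#>   origins: A
#>   destinies: C

# a 3-chain compared against a 10-chain containing A, B, C in order
r <- compare_pair(fx$chain3, fx$chain10, "A", "C",
                  origins(fx$chain10), destinies(fx$chain10))
print(r)
#> <comparison_report> chain3 (A=>C) vs chain10 (N01=>N07)
#>   relative global 0.300 | local 0.333 | semiglobal 0.000 | numerical DbP 1.000
#>   size ratio 0.300 (different), equivalent nodes 0.300, common families 0 (none)
```

The relative global score 0.30 is exactly the size ratio 3/10: all three
labels of the smaller pathway occur in analogous order in the larger one,
which is the best any 3-vs-10 comparison can do. The local score finds
the single best shared segment (one label, 1/3). The semi-global score is
0 here because the shared labels sit in the *interior* of the longer
traversal — free end gaps only help when one sequence overlaps an end of
the other. The numerical DbP of 1.0 records that no *reaction* (edge) is
shared even though three metabolites are — the two methods answer
different questions.

Aligning two traversals directly:

```r
a <- align_global(c("A","B","C"), c("A","P","B","Q","C"), scoring_scheme(1, -1, 0))
print(a)
#> <pathway_alignment> global: score=3 relative=0.6000 (x=3 y=0 z=2)
#>   S: A - B - C
#>   T: A P B Q C
```

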