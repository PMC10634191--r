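---
title: "Relative divergence-time graphs and explaining scenarios"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Relative divergence-time graphs and explaining scenarios}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(edtgraph)
```

## The model

A **relaxed scenario** describes the history of a gene family inside a species
phylogeny.  It bundles a dated gene tree $(T, \tau_T)$, a dated species tree
$(S, \tau_S)$, a coloring $\sigma$ assigning each extant gene to the species
in which it resides, and a reconciliation $\mu$ mapping every gene-tree vertex
to a vertex or an edge of $S$.  Both trees are *planted*: an extra degree-one
root above the conventional root accommodates events predating the first
divergence.  Time consistency is the only constraint:

* S0 — the planted roots correspond under $\mu$;
* S1 — leaves map to leaves, namely to $\sigma$;
* S2 — a vertex image forces equal stamps, $\tau_S(\mu(x)) = \tau_T(x)$;
* S3 — an edge image $(u,v)$ brackets the stamp, $\tau_S(v) < \tau_T(x) < \tau_S(u)$.

No ancestor-preservation is imposed: a gene edge whose endpoints map to
incomparable locations of $S$ is a **horizontal transfer (HGT) edge**.
**Restricted scenarios** additionally satisfy the witness axioms: every vertex
retains a descendant reachable without crossing a transfer (S4), children of
speciation-like vertices map strictly below (S5), and every speciation-like
vertex is witnessed by a leaf pair whose gene and species last common
ancestors coincide (S6).

For each pair of genes $x, y$ the stamp of $\mathrm{lca}_T(x,y)$ is compared
with the stamp of $\mathrm{lca}_S(\sigma(x), \sigma(y))$, partitioning all
pairs into three vertex-colored graphs: the **LDT** graph (gene divergence
*later*), the **EDT** graph (*equal*), and the **PDT** graph (*prior*).
`divergence_partition()` computes this 3-partition; it is the package's
central object.

```{r}
s <- fixture("star_example")
divergence_partition(s)
```

## What can be decided, and how

* **Explainability** (`is_valid_input`): a 3-partition is explained by some
  relaxed scenario iff LDT and EDT graphs are properly colored, LDT and PDT
  graphs are cographs (no induced $P_4$), and the *species triple system*
  read off the partition is consistent.  Triples are extracted by
  `gene_triples()` / `species_triples()`: LDT cherries and isolated PDT edges
  force species triples, unequal EDT paths forbid them.
* **Construction** (`build_scenario`): a species tree agreeing with the
  triples is found by a mixed-triples recursion (`mixed_tree`), dated with
  leaves at 0 and internal vertices at `scale = 3` per height level, and the
  gene tree is grown top-down over three nested auxiliary graphs
  (`auxiliary_graphs`).  New stamps are placed at $\tau_S(u_S) \pm \epsilon$
  with $\epsilon$ = one third of the minimum species edge duration
  (`epsilon_margin`), which keeps every placement strictly inside the
  adjacent edges.  With `restricted = TRUE` one otherwise free choice of the
  child edge is anchored so that S4–S6 hold.
* **Recognition of single graphs**: `recognize_pdt` and
  `recognize_edt_hgt_free` decide in polynomial time whether a colored graph
  is the PDT graph of some scenario, or the EDT graph of a transfer-free
  scenario; `recognize_ldt` reduces through the partition machinery.  General
  EDT recognition is NP-complete, so `edt_oracle` enumerates the undetermined
  non-edges exhaustively on small instances (refusing, distinctly from a
  "no", beyond `max_free_pairs`).
* **Orthology variants**: `quasi_orthology` and `orthology` compute the four
  graphs obtained by requiring the gene pair's last common ancestor to map to
  *some* inner species vertex (weak) or exactly to the species lca (strict),
  with or without excluding transfer-crossing paths; `fitch_graph` is the
  complementary xenology notion.  All variants except the strict
  quasi-orthology graph are cographs; the strict quasi-orthology graph equals
  the EDT graph on generic scenarios.

## Parameters that matter

| parameter | where | default | why |
|---|---|---|---|
| `scale` | `assign_time_map`, `build_scenario` | 3 time units per height level | reproduces the worked builder trace bit-exactly (species root at 3, planted root at 6, $\epsilon = 1$) |
| $\epsilon$ rule | `epsilon_margin` | $d_{\min}/3$ | the theory only needs "sufficiently small"; $d_{\min}/3$ guarantees $2\epsilon$ fits inside every edge and matches the worked trace |
| `edtgraph.tol` option | all stamp comparisons | `1e-9` absolute | stamps are doubles, not exact rationals; the simulator keeps all event stamps at least `1e-3` away from species stamps, so the tolerance never decides a comparison on generated data.  Set the option if you feed in empirically dated scenarios |
| `max_free_pairs` | `edt_oracle` | 20 | the exhaustive completion search is exponential; 20 free pairs is the largest instance that stays interactive |
| size guards | `structural_report` | paths ≤ 14 vertices, holes ≤ 11 | exhaustive induced-subgraph searches; above the guard the field is `NA` with an explicit note, never silently truncated |

## The simulator: what it emulates and what it does not

`random_scenario()` grows a gene tree forward in time inside a random dated
species tree.  Per species-edge traversal a lineage may duplicate
(probability `dup_prob`) or transfer a copy to a contemporaneous incomparable
species edge (`transfer_prob`; silently skipped when no such edge exists, as
for lineages above the first speciation).  At a speciation vertex the lineage
is reconciled with the vertex and continues into every child edge; with
probability `lump_prob` one child edge receives an extra copy.  This last
move deserves justification: relaxed scenarios explicitly allow a vertex
reconciled with a speciation vertex to have several descendants in the same
lineage, and it is exactly these configurations that realize non-cograph EDT
graphs (induced $P_4$s, 6-cycles and induced 5-vertex paths).  A generator
restricted to "clean" events would make large parts of the theory vacuously
true on simulated data; `lump_prob = 0.15` makes roughly 3% of small
scenarios carry an induced path on 5 vertices, matching the proved extremum.

Event stamps are jittered uniformly, rejected within `1e-3` of any species
stamp, and inner species stamps are made pairwise distinct — so generated
scenarios are **generic by construction** (equal stamps imply equal
reconciliation), which the orthology results require.  `jitter = FALSE`
instead parks event stamps on species stamps whenever possible, producing
non-generic cases for negative tests.  The gene count is hit exactly by
boosted-duplication retries, terminal leaf splits, or uniform pruning.

The generator emulates *relative timing structure only*.  It does not model
branch lengths, molecular clocks, birth–death dynamics, gene loss as an
explicit event (losses appear implicitly through pruning), or sequence
evolution.  A green property suite therefore establishes the combinatorial
theory on the reachable class of valid scenarios — it says nothing about
statistical realism of the event rates.

## Numerical and degenerate-input choices

* Deterministic tie-breaking everywhere: components and blocks are ordered by
  smallest contained label (byte order), the restricted builder anchors the
  lexicographically smallest straddling pair, and the default child choice
  takes the child subtree holding the smallest color.  Any agreeing species
  tree and any valid child choice would do; determinism is for
  reproducibility, not correctness.
* A single-gene partition builds the one-leaf scenario; an empty gene set is
  an error.  Single-species trees are planted leaves and fully supported.
* `mixed_tree` merges Aho components to a least fixed point under
  "if a forbidden triple's cherry is joined, its outgroup joins too"; if
  everything collapses into one block no agreeing tree exists.  Correctness
  is cross-checked against exhaustive enumeration of all rooted trees on up
  to six labels.
* Suppression of unary vertices splices each dropped vertex's unique child to
  its current parent; chains resolve because both pointers are read at
  processing time.

## Known limitations

* General EDT recognition is only available at desk scale (`edt_oracle`); the
  problem is NP-complete and no heuristic for large instances is provided.
* The cograph test is the recursive complement-decomposition check with a
  quartic certificate search on failure — quadratic-time modular
  decomposition is not implemented; fine for gene families of tens of genes.
* Event-type labels (speciation / duplication / transfer tags on gene
  vertices) are deliberately out of scope: relaxed scenarios do not determine
  them uniquely.
* Stamps are compared with an absolute tolerance; data with stamps closer
  than `1e-9` must rescale or adjust `options(edtgraph.tol=)`.
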