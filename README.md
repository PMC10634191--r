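# edtgraph

Relative timing of gene and species divergences in evolutionary scenarios:
equal- (EDT), later- (LDT) and prior-divergence-time (PDT) graphs, their
structural theory, and the construction of time-consistent reconciliation
scenarios that explain them.

## The problem

For a gene family evolving inside a species phylogeny, the *relative* order of
two divergences — the split of two genes $x, y$ versus the split of the
species $\sigma(x), \sigma(y)$ they reside in — can be estimated from sequence
data and is informative about horizontal gene transfer (later divergence) and
ancient duplication (prior divergence), while *equal* divergence time is a
necessary condition for orthology.  Comparing
$\tau_T(\mathrm{lca}_T(x,y))$ with $\tau_S(\mathrm{lca}_S(\sigma x, \sigma y))$
for all pairs partitions the complete graph on the genes into three
vertex-colored graphs $(G_<, G_=, G_>, \sigma)$.

This package answers, for such data:

* Is a given 3-partition explainable by a **relaxed scenario**
  $(T, S, \sigma, \mu, \tau_T, \tau_S)$ — a reconciliation constrained only by
  time consistency?  (Yes iff $G_<, G_=$ are properly colored, $G_<, G_>$ are
  cographs, and the species triples read off the partition are consistent.)
* If so, construct one — and even a **restricted** scenario in which every
  vertex has a transfer-free witness and speciations are anchored by leaf
  pairs with matching last common ancestors.
* Which single graphs arise as PDT graphs, or as EDT graphs of transfer-free
  scenarios (both decidable in polynomial time), and small-instance exhaustive
  recognition of general EDT graphs (NP-complete in general)?
* How do the four orthology variants (weak/strict, quasi/strict-sense) and the
  symmetrized Fitch xenology graph relate to $G_=$ and $G_<$?

It is aimed at researchers in phylogenomics / mathematical phylogenetics who
want a reference implementation of this theory with its invariants wired up as
executable property tests.

## Worked example

The 4-gene, 2-species partition with LDT edges $\{ab, a'b'\}$, EDT edges
$\{ab', a'b\}$ and PDT edges $\{aa', bb'\}$:

```r
library(edtgraph)
g <- fixture("fig9_partition")
is_valid_input(g)$explainable
#> [1] TRUE

s <- build_scenario(g, restricted = TRUE)
attr(s, "trace")$epsilon
#> [1] 1
write_newick(s$gene_tree)
#> [1] "((a,b),(a',b'));"
partitions_ok <- identical(divergence_partition(s)$rel[order(names(g$rel))],
                           g$rel[order(names(g$rel))])
partitions_ok
#> [1] TRUE
nrow(validate_restricted(s))   # S4-S6 all hold
#> [1] 0
```

The builder dates the species tree with leaves at 0, root at 3 and planted
root at 6, computes the safety margin $\epsilon = 1$ (one third of the
minimum edge duration), places the top recursion root at stamp $3 + \epsilon =
4$ on the planted species edge, the first gene vertex below the species root
at $3 - \epsilon = 2$, and the leaf-level recursion roots at $0 + \epsilon =
1$ — and the resulting scenario's divergence partition reproduces the input
exactly.

Simulation and recognition:

```r
s <- random_scenario(n_species = 5, n_genes = 12, transfer_prob = 0.3, seed = 7)
g <- divergence_partition(s)
isTRUE(is_cograph(g$ldt)) && isTRUE(is_cograph(g$pdt))
#> [1] TRUE
cert <- recognize_pdt(g$pdt)       # certificate scenario, not a bare verdict
is.null(cert)
#> [1] FALSE
```

A command-line wrapper (`inst/scripts/edt`) exposes
`simulate | check | build | recognize | orthology` over TSV graphs and JSON
scenario bundles; see `?edt_cli`.

## Scope

Event-type labeling of gene-tree vertices, parsimony costs, probabilistic
reconciliation, and branch-length-based dating are out of scope.  See the
methods vignette (`vignettes/divergence-time-graphs.Rmd`) for the model,
parameter choices and limitations.
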