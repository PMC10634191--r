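# Orthology-flavoured graphs of a scenario.
#
# Four variants: the gene pair's last common ancestor may be required to map
# to *some* inner species vertex (weak) or to exactly the species last common
# ancestor (strict), with ("ortholog") or without ("quasi-ortholog") the
# additional requirement that the connecting path is free of HGT edges.
# The symmetrized Fitch graph is the complementary notion: pairs separated by
# at least one transfer.

.leaf_pairs <- function(s) {
  leaves <- sort(tree_leaves(s$gene_tree), method = "radix")
  if (length(leaves) < 2) return(matrix(character(0), ncol = 2))
  t(utils::combn(leaves, 2))
}

.hgt_lam <- function(s) {
  h <- hgt_edges(s)
  stats::setNames(h$lam, h$edges[, "child"])
}

.path_has_hgt <- function(s, x, y, lam = .hgt_lam(s)) {
  T <- s$gene_tree
  top <- v_index(T, tree_lca(T, c(x, y)))
  climb <- function(leaf) {
    v <- v_index(T, leaf)
    while (v != top) {
      if (lam[[T$labels[v]]] == 1L) return(TRUE)
      v <- T$parent[v]
    }
    FALSE
  }
  climb(x) || climb(y)
}

.ortho_graph <- function(s, strict, exclude_hgt) {
  T <- s$gene_tree; S <- s$species_tree
  inner_S <- tree_inner(S)
  prs <- .leaf_pairs(s)
  lam <- if (exclude_hgt) .hgt_lam(s) else NULL
  keep <- logical(nrow(prs))
  for (r in seq_len(nrow(prs))) {
    x <- prs[r, 1]; y <- prs[r, 2]
    m <- s$mu[[tree_lca(T, c(x, y))]]
    ok <- if (strict) {
      !loc_is_edge(m) && m == tree_lca(S, c(s$sigma[[x]], s$sigma[[y]]))
    } else {
      !loc_is_edge(m) && m %in% inner_S
    }
    if (ok && exclude_hgt) ok <- !.path_has_hgt(s, x, y, lam)
    keep[r] <- ok
  }
  colored_graph(sort(tree_leaves(T), method = "radix"),
                prs[keep, , drop = FALSE], s$sigma)
}

#' Quasi-orthology graphs
#'
#' Weak quasi-orthologs: gene pairs whose last common ancestor is reconciled
#' with an inner vertex of the species tree.  Strict quasi-orthologs: the
#' reconciled vertex is exactly the species last common ancestor of their
#' colors.  The strict graph is always a subgraph of both the weak graph and
#' the scenario's EDT graph, and equals the EDT graph for generic scenarios.
#'
#' @param s an `edt_scenario`.
#' @param strict require the species lca to match?
#' @return a `colored_graph` on the gene leaves.
#' @export
quasi_orthology <- function(s, strict = FALSE) .ortho_graph(s, strict, FALSE)

#' Orthology graphs
#'
#' Like [quasi_orthology()] but additionally requiring that the path between
#' the two genes contains no HGT edge.  The weak and strict orthology graphs
#' are cographs for every scenario.
#'
#' @param s an `edt_scenario`.
#' @param strict require the species lca to match?
#' @return a `colored_graph` on the gene leaves.
#' @export
orthology <- function(s, strict = FALSE) .ortho_graph(s, strict, TRUE)

#' Symmetrized Fitch (xenology) graph
#'
#' Joins two genes precisely when the path between them in the gene tree
#' contains at least one HGT edge.  Always a complete multipartite graph and
#' a supergraph of the scenario's LDT graph.
#'
#' @param s an `edt_scenario`.
#' @return a `colored_graph` on the gene leaves.
#' @export
fitch_graph <- function(s) {
  prs <- .leaf_pairs(s)
  lam <- .hgt_lam(s)
  keep <- logical(nrow(prs))
  for (r in seq_len(nrow(prs))) {
    keep[r] <- .path_has_hgt(s, prs[r, 1], prs[r, 2], lam)
  }
  colored_graph(sort(tree_leaves(s$gene_tree), method = "radix"),
                prs[keep, , drop = FALSE], s$sigma)
}
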