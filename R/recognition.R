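# Decision procedures for single divergence-time graphs.
#
# PDT graphs and HGT-free EDT graphs are recognizable in polynomial time;
# general EDT recognition is hard, so a small-instance exhaustive oracle over
# the undetermined non-edges is provided instead.  All recognizers return a
# constructed certificate scenario rather than a bare verdict.

#' Recognize a PDT graph
#'
#' `(G, sigma)` is the PDT graph of some relaxed scenario iff G is a cograph,
#' the complement of G is properly colored, and the species triples read off
#' G (pair in G, both cross pairs outside, colors pairwise distinct) are
#' consistent.  On success a scenario explaining the partition
#' (complement, empty, G) is returned; its PDT graph equals the input.
#'
#' @param G a `colored_graph`.
#' @return an `edt_scenario` or `NULL`.
#' @export
recognize_pdt <- function(G) {
  empty <- colored_graph(G$vertices, NULL, G$sigma)
  g <- three_partition(graph_complement(G), empty, G)
  v <- is_valid_input(g)
  if (!v$explainable) return(NULL)
  build_scenario(g)
}

#' Recognize an EDT graph explainable without horizontal transfer
#'
#' `(G, sigma)` is the EDT graph of some HGT-free relaxed scenario iff it is
#' a properly colored cograph and the triple set
#' `{sigma(x)sigma(y)|sigma(z) : xz, yz edges, xy non-edge, colors distinct}`
#' is consistent (checked with BUILD).  On success the partition
#' (empty, G, complement) is explained by a restricted scenario, which is
#' fully witnessed with an edgeless LDT graph and therefore HGT-free.
#'
#' @param G a `colored_graph`.
#' @return an HGT-free `edt_scenario` or `NULL`.
#' @export
recognize_edt_hgt_free <- function(G) {
  if (!is_properly_colored(G) || !isTRUE(is_cograph(G))) return(NULL)
  # triple set of Thm-14 shape, checked independently of the builder's
  # mixed-triple machinery
  adj <- graph_adjacency(G)
  v <- G$vertices
  ra <- rb <- ro <- character(0)
  if (length(v) >= 3) {
    trips <- utils::combn(v, 3)
    for (j in seq_len(ncol(trips))) {
      t <- trips[, j]
      if (length(unique(G$sigma[t])) < 3) next
      for (k in 1:3) {
        z <- t[k]; xy <- t[-k]
        if (adj[xy[1], z] && adj[xy[2], z] && !adj[xy[1], xy[2]]) {
          ra <- c(ra, G$sigma[[xy[1]]]); rb <- c(rb, G$sigma[[xy[2]]])
          ro <- c(ro, G$sigma[[z]])
        }
      }
    }
  }
  R <- triple_df(ra, rb, ro)
  if (is.null(aho_build(R, unique(unname(G$sigma))))) return(NULL)
  empty <- colored_graph(G$vertices, NULL, G$sigma)
  g <- three_partition(empty, G, graph_complement(G))
  out <- build_scenario(g, restricted = TRUE)
  if (!is_hgt_free(out)) stop("internal error: restricted explanation not HGT-free")
  out
}

#' Recognize an LDT graph
#'
#' Reduction through the 3-partition machinery: `(G, sigma)` is an LDT graph
#' iff the partition (G, empty, complement) is explainable.
#'
#' @param G a `colored_graph`.
#' @return an `edt_scenario` or `NULL`.
#' @export
recognize_ldt <- function(G) {
  empty <- colored_graph(G$vertices, NULL, G$sigma)
  g <- three_partition(G, empty, graph_complement(G))
  v <- is_valid_input(g)
  if (!v$explainable) return(NULL)
  build_scenario(g)
}

#' Small-instance exhaustive EDT recognizer
#'
#' General EDT recognition (without knowledge of the LDT/PDT side) is
#' NP-complete, so this oracle is restricted to small inputs.  Non-edges
#' between distinct connected components of G, and all same-colored pairs,
#' may be fixed to the PDT side without loss of generality; the remaining
#' non-edges are assigned to LDT/PDT exhaustively and each completion is
#' tested for explainability.  Necessary conditions (proper coloring,
#' P6-freeness, odd-hole-freeness) short-circuit the search.
#'
#' @param G a `colored_graph`.
#' @param max_free_pairs refuse (with an error of class
#'   `"edtgraph_budget_error"`) when more than this many non-edges remain
#'   undetermined; a refusal is distinct from a `NULL` verdict.
#' @return an explaining `edt_scenario` with `G` as its EDT graph, or `NULL`
#'   when no relaxed scenario explains `G`.
#' @export
edt_oracle <- function(G, max_free_pairs = 20) {
  if (!is_properly_colored(G)) return(NULL)
  adj <- graph_adjacency(G)
  n <- length(G$vertices)
  if (n <= 14 && longest_induced_path_adj(adj) >= 6) return(NULL)
  if (n <= 11 && .has_odd_hole(adj)) return(NULL)
  comps <- adj_components(adj)
  comp_id <- integer(n)
  for (i in seq_along(comps)) comp_id[comps[[i]]] <- i
  v <- G$vertices
  fixed_gt <- matrix(character(0), ncol = 2)
  free <- matrix(character(0), ncol = 2)
  if (n >= 2) {
    prs <- utils::combn(seq_len(n), 2)
    for (j in seq_len(ncol(prs))) {
      a <- prs[1, j]; b <- prs[2, j]
      if (adj[a, b]) next
      if (comp_id[a] != comp_id[b] || G$sigma[[v[a]]] == G$sigma[[v[b]]]) {
        fixed_gt <- rbind(fixed_gt, c(v[a], v[b]))
      } else {
        free <- rbind(free, c(v[a], v[b]))
      }
    }
  }
  k <- nrow(free)
  if (k > max_free_pairs) {
    stop(structure(class = c("edtgraph_budget_error", "error", "condition"),
                   list(message = sprintf(
                     "%d undetermined non-edges exceed the budget of %d",
                     k, max_free_pairs), call = sys.call())))
  }
  for (mask in 0:(2^k - 1)) {
    bits <- if (k == 0) logical(0) else as.logical(bitwAnd(mask, 2^(seq_len(k) - 1)))
    lt_edges <- free[!bits, , drop = FALSE]
    gt_edges <- rbind(fixed_gt, free[bits, , drop = FALSE])
    g <- three_partition(colored_graph(v, lt_edges, G$sigma),
                         G,
                         colored_graph(v, gt_edges, G$sigma))
    if (is_valid_input(g)$explainable) return(build_scenario(g))
  }
  NULL
}
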