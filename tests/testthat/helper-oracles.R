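# Independent oracles and small utilities shared by the test files.
# These deliberately re-derive quantities by different (usually brute-force)
# routes than the package implementation.

# --- random rooted trees (own generator, not the package simulator) ---------
rand_nested_tree <- function(labels) {
  # random recursive partition into 2-3 blocks
  if (length(labels) == 1) return(labels)
  k <- if (length(labels) == 2) 2 else sample(2:min(3, length(labels)), 1)
  blocks <- split(labels, sample(rep(seq_len(k), length.out = length(labels))))
  blocks <- Filter(function(b) length(b) > 0, blocks)
  if (length(blocks) == 1) return(rand_nested_tree(labels))
  lapply(unname(blocks), rand_nested_tree)
}

rand_tree <- function(n) {
  labs <- paste0("l", seq_len(n))
  edtgraph:::tree_from_nested(rand_nested_tree(labs))
}

# --- lca oracle: explicit root-to-leaf paths --------------------------------
oracle_lca <- function(tree, A) {
  paths <- lapply(A, function(x) {
    p <- character(0)
    i <- match(x, tree$labels)
    while (!is.na(i)) {
      p <- c(tree$labels[i], p)  # root first
      i <- tree$parent[i]
    }
    p
  })
  depth <- min(lengths(paths))
  common <- NA_character_
  for (d in seq_len(depth)) {
    step <- vapply(paths, `[`, character(1), d)
    if (length(unique(step)) == 1) common <- step[1] else break
  }
  common
}

# --- restriction oracle: recursive partition by child subtrees --------------
oracle_restrict_canonical <- function(tree, leaves) {
  subl <- edtgraph:::.subtree_leaves(tree)
  rec <- function(keep) {
    if (length(keep) == 1) return(keep)
    top <- oracle_lca(tree, keep)
    ti <- match(top, tree$labels)
    parts <- character(0)
    for (c in tree$children[[ti]]) {
      sub <- intersect(keep, subl[[c]])
      if (length(sub) > 0) parts <- c(parts, rec(sub))
    }
    paste0("(", paste(sort(parts, method = "radix"), collapse = ","), ")")
  }
  rec(sort(leaves, method = "radix"))
}

# --- brute-force induced-P4 search ------------------------------------------
oracle_has_p4 <- function(g) {
  adj <- edtgraph:::graph_adjacency(g)
  v <- seq_len(nrow(adj))
  if (length(v) < 4) return(FALSE)
  for (q in utils::combn(v, 4, simplify = FALSE)) {
    for (p in list(q, q[c(1,2,4,3)], q[c(1,3,2,4)], q[c(1,3,4,2)],
                   q[c(1,4,2,3)], q[c(1,4,3,2)], q[c(2,1,3,4)],
                   q[c(2,1,4,3)], q[c(2,3,1,4)], q[c(2,4,1,3)],
                   q[c(3,1,2,4)], q[c(3,2,1,4)])) {
      if (adj[p[1], p[2]] && adj[p[2], p[3]] && adj[p[3], p[4]] &&
          !adj[p[1], p[3]] && !adj[p[1], p[4]] && !adj[p[2], p[4]]) {
        return(TRUE)
      }
    }
  }
  FALSE
}

# --- displayed-triple tables over enumerated trees --------------------------
# for a tree and label set, the set of keys "x|y|z" (x<y) of displayed
# rooted triples
displayed_triple_keys <- function(tree, labels) {
  keys <- character(0)
  if (length(labels) < 3) return(keys)
  for (t in utils::combn(sort(labels, method = "radix"), 3, simplify = FALSE)) {
    for (k in 1:3) {
      z <- t[k]; xy <- t[-k]
      if (tree_displays(tree, rooted_triple(xy[1], xy[2], z))) {
        keys <- c(keys, paste(xy[1], xy[2], z, sep = "|"))
      }
    }
  }
  keys
}

triple_df_keys <- function(df) paste(df$a, df$b, df$out, sep = "|")

triple_df_make <- function(x, y, z) edtgraph:::triple_df(x, y, z)

# --- random colored graph ----------------------------------------------------
rand_colored_graph <- function(n, p = 0.4, n_colors = max(2, n %/% 2)) {
  v <- paste0("x", seq_len(n))
  sig <- stats::setNames(sample(paste0("C", seq_len(n_colors)), n, replace = TRUE), v)
  prs <- t(utils::combn(v, 2))
  keep <- stats::runif(nrow(prs)) < p
  colored_graph(v, prs[keep, , drop = FALSE], sig)
}

# --- partition equality ------------------------------------------------------
partitions_equal <- function(g1, g2) {
  identical(sort(names(g1$rel)), sort(names(g2$rel))) &&
    identical(g1$rel[sort(names(g1$rel))], g2$rel[sort(names(g2$rel))]) &&
    identical(g1$sigma, g2$sigma)
}

graph_subset <- function(g1, g2) {
  # edge set of g1 contained in edge set of g2
  k1 <- if (nrow(g1$edges) == 0) character(0) else
    edtgraph:::pair_key(g1$edges[, 1], g1$edges[, 2])
  k2 <- if (nrow(g2$edges) == 0) character(0) else
    edtgraph:::pair_key(g2$edges[, 1], g2$edges[, 2])
  all(k1 %in% k2)
}

graphs_equal_edges <- function(g1, g2) {
  graph_subset(g1, g2) && graph_subset(g2, g1)
}

# --- shared simulation batches ----------------------------------------------
sim_batch <- function(n_scen, seed_offset = 0, genes = 5:25, species = 3:8,
                      ...) {
  lapply(seq_len(n_scen), function(i) {
    tp <- c(0, 0.1, 0.25, 0.4, 0.5)[(i %% 5) + 1]
    dp <- c(0.1, 0.2, 0.3)[(i %% 3) + 1]
    random_scenario(species[(i %% length(species)) + 1],
                    genes[(i %% length(genes)) + 1],
                    transfer_prob = tp, dup_prob = dp,
                    seed = i + seed_offset, ...)
  })
}
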