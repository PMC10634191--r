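# Vertex-colored graphs and graph 3-partitions.
#
# Graphs are small (gene families), so edges are stored as a canonical
# two-column character matrix (u < v in radix order) and most algorithms run
# on logical adjacency matrices.

pair_key <- function(u, v) {
  swap <- u > v
  a <- ifelse(swap, v, u); b <- ifelse(swap, u, v)
  paste(a, b, sep = "\r")
}

canon_pairs <- function(edges) {
  # edges: 2-column character matrix (possibly 0 rows); returns canonical
  # sorted unique matrix
  if (is.null(edges) || length(edges) == 0) {
    return(matrix(character(0), ncol = 2, dimnames = list(NULL, c("u", "v"))))
  }
  edges <- matrix(as.character(edges), ncol = 2)
  swap <- edges[, 1] > edges[, 2]
  edges[swap, ] <- edges[swap, 2:1]
  if (any(edges[, 1] == edges[, 2])) stop("self-loops are not allowed")
  keys <- paste(edges[, 1], edges[, 2], sep = "\r")
  edges <- edges[!duplicated(keys), , drop = FALSE]
  edges <- edges[order(edges[, 1], edges[, 2], method = "radix"), , drop = FALSE]
  colnames(edges) <- c("u", "v")
  edges
}

#' Construct a vertex-colored graph
#'
#' @param vertices character vector of vertex labels.
#' @param edges two-column character matrix (or an empty value) of unordered
#'   edges; self-loops are rejected.
#' @param sigma named character vector assigning a color (species label) to
#'   every vertex.
#' @return an object of class `colored_graph`.
#' @export
colored_graph <- function(vertices, edges, sigma) {
  vertices <- as.character(vertices)
  if (anyDuplicated(vertices) > 0) stop("duplicate vertex labels")
  edges <- canon_pairs(edges)
  if (length(edges) > 0 && !all(c(edges) %in% vertices)) {
    stop("edges refer to undeclared vertices")
  }
  if (!all(vertices %in% names(sigma))) stop("sigma must color every vertex")
  vertices <- sort(vertices, method = "radix")
  sigma <- stats::setNames(as.character(sigma[vertices]), vertices)
  structure(list(vertices = vertices, edges = edges, sigma = sigma),
            class = "colored_graph")
}

#' @export
print.colored_graph <- function(x, ...) {
  cat("colored graph:", length(x$vertices), "vertices,",
      nrow(x$edges), "edges,", length(unique(x$sigma)), "colors\n")
  invisible(x)
}

graph_adjacency <- function(g) {
  n <- length(g$vertices)
  adj <- matrix(FALSE, n, n, dimnames = list(g$vertices, g$vertices))
  if (nrow(g$edges) > 0) {
    adj[g$edges] <- TRUE
    adj[g$edges[, 2:1, drop = FALSE]] <- TRUE
  }
  adj
}

adj_to_edges <- function(adj) {
  idx <- which(adj & upper.tri(adj), arr.ind = TRUE)
  cbind(u = rownames(adj)[idx[, 1]], v = colnames(adj)[idx[, 2]])
}

#' Complement of a colored graph
#' @param g a `colored_graph`.
#' @return a `colored_graph` on the same vertices and coloring.
#' @export
graph_complement <- function(g) {
  adj <- !graph_adjacency(g)
  diag(adj) <- FALSE
  colored_graph(g$vertices, adj_to_edges(adj), g$sigma)
}

#' Induced subgraph of a colored graph
#' @param g a `colored_graph`.
#' @param vs vertex subset.
#' @return a `colored_graph`.
#' @export
graph_induced <- function(g, vs) {
  vs <- as.character(vs)
  if (!all(vs %in% g$vertices)) stop("unknown vertices in restriction")
  keep <- g$edges[, 1] %in% vs & g$edges[, 2] %in% vs
  colored_graph(vs, g$edges[keep, , drop = FALSE], g$sigma[vs])
}

#' Is a colored graph properly colored?
#'
#' TRUE precisely when no edge joins two vertices of the same color.  LDT and
#' EDT graphs of valid scenarios always are; PDT graphs generally are not.
#'
#' @param g a `colored_graph`.
#' @return logical scalar.
#' @export
is_properly_colored <- function(g) {
  if (nrow(g$edges) == 0) return(TRUE)
  !any(g$sigma[g$edges[, 1]] == g$sigma[g$edges[, 2]])
}

# connected components of a logical adjacency matrix restricted to idx;
# returns a list of integer index vectors
adj_components <- function(adj, idx = seq_len(nrow(adj))) {
  comps <- list()
  left <- idx
  while (length(left) > 0) {
    seed <- left[1]
    comp <- seed
    frontier <- seed
    left <- left[-1]
    while (length(frontier) > 0 && length(left) > 0) {
      nxt <- left[colSums(adj[frontier, left, drop = FALSE]) > 0]
      frontier <- nxt
      comp <- c(comp, nxt)
      left <- setdiff(left, nxt)
    }
    comps[[length(comps) + 1L]] <- sort(comp)
  }
  comps
}

# cograph test on a logical adjacency matrix; TRUE/FALSE
.is_cograph_adj <- function(adj, idx = seq_len(nrow(adj))) {
  n <- length(idx)
  if (n <= 3) return(TRUE)
  comps <- adj_components(adj, idx)
  if (length(comps) > 1) {
    return(all(vapply(comps, function(c) .is_cograph_adj(adj, c), logical(1))))
  }
  co <- !adj
  diag(co) <- FALSE
  cocomps <- adj_components(co, idx)
  if (length(cocomps) > 1) {
    return(all(vapply(cocomps, function(c) .is_cograph_adj(adj, c), logical(1))))
  }
  FALSE
}

# brute-force search for one induced P4 among idx; returns labels in path
# order or NULL
.find_p4 <- function(adj, idx = seq_len(nrow(adj))) {
  if (length(idx) < 4) return(NULL)
  quads <- utils::combn(idx, 4)
  perms <- list(c(1, 2, 3, 4), c(1, 2, 4, 3), c(1, 3, 2, 4),
                c(1, 3, 4, 2), c(1, 4, 2, 3), c(1, 4, 3, 2),
                c(2, 1, 3, 4), c(2, 1, 4, 3), c(2, 3, 1, 4),
                c(2, 4, 1, 3), c(3, 1, 2, 4), c(3, 2, 1, 4))
  for (q in seq_len(ncol(quads))) {
    v <- quads[, q]
    deg <- c(sum(adj[v[1], v[-1]]), sum(adj[v[2], v[-2]]),
             sum(adj[v[3], v[-3]]), sum(adj[v[4], v[-4]]))
    if (sum(deg) != 6 || max(deg) != 2 || min(deg) != 1) next
    for (p in perms) {
      w <- v[p]
      if (adj[w[1], w[2]] && adj[w[2], w[3]] && adj[w[3], w[4]] &&
          !adj[w[1], w[3]] && !adj[w[1], w[4]] && !adj[w[2], w[4]]) {
        return(rownames(adj)[w])
      }
    }
  }
  NULL
}

#' Cograph (P4-free) test with certificate
#'
#' Uses the recursive complement-decomposition characterization: a graph is a
#' cograph iff every induced subgraph on >= 2 vertices is disconnected or
#' co-disconnected.  When the graph is not a cograph, a witnessing induced
#' path on four vertices is attached as attribute `"p4"`.
#'
#' @param g a `colored_graph` (the coloring is ignored).
#' @return logical scalar; if `FALSE`, `attr(., "p4")` holds a certificate
#'   (labels in path order).
#' @export
is_cograph <- function(g) {
  adj <- graph_adjacency(g)
  ok <- .is_cograph_adj(adj)
  if (ok) return(TRUE)
  structure(FALSE, p4 = .find_p4(adj))
}

# longest induced path (vertex count) via DFS extension.  EDT graphs cannot
# contain induced paths on 6 vertices, so the search tree stays shallow on
# the graphs this package produces.
longest_induced_path_adj <- function(adj) {
  n <- nrow(adj)
  if (n == 0) return(0L)
  best <- 1L
  extend <- function(path) {
    best <<- max(best, length(path))
    last <- path[length(path)]
    cand <- which(adj[last, ])
    cand <- cand[!(cand %in% path)]
    for (w in cand) {
      if (length(path) > 1 && any(adj[w, path[-length(path)]])) next
      extend(c(path, w))
    }
  }
  for (v in seq_len(n)) extend(v)
  as.integer(best)
}

# any induced cycle with odd length >= 5 among the whole graph? exhaustive
# subset enumeration; intended for n <= ~11
.has_odd_hole <- function(adj) {
  n <- nrow(adj)
  if (n < 5) return(FALSE)
  for (k in seq(5, n, by = 2)) {
    if (k > n) break
    subs <- utils::combn(seq_len(n), k)
    for (j in seq_len(ncol(subs))) {
      s <- subs[, j]
      sub <- adj[s, s, drop = FALSE]
      if (all(rowSums(sub) == 2) && length(adj_components(sub)) == 1) {
        return(TRUE)
      }
    }
  }
  FALSE
}

#' Graph 3-partition of all vertex pairs
#'
#' Bundles the LDT graph (gene pair diverged later than the species pair),
#' the EDT graph (equal divergence times) and the PDT graph (gene divergence
#' prior to species divergence).  The three edge sets must partition all
#' unordered vertex pairs.
#'
#' @param ldt,edt,pdt `colored_graph`s on identical vertices and coloring.
#' @return an object of class `three_partition` with elements `ldt`, `edt`,
#'   `pdt`, `vertices`, `sigma`, and a named relation vector `rel` over pair
#'   keys with values `"LT"`, `"EQ"`, `"GT"`.
#' @export
three_partition <- function(ldt, edt, pdt) {
  stopifnot(inherits(ldt, "colored_graph"), inherits(edt, "colored_graph"),
            inherits(pdt, "colored_graph"))
  v <- ldt$vertices
  if (!identical(v, edt$vertices) || !identical(v, pdt$vertices)) {
    stop("the three graphs must share one vertex set")
  }
  if (!identical(ldt$sigma, edt$sigma) || !identical(ldt$sigma, pdt$sigma)) {
    stop("the three graphs must share one coloring")
  }
  rel <- character(0)
  add <- function(rel, g, tag) {
    if (nrow(g$edges) == 0) return(rel)
    k <- pair_key(g$edges[, 1], g$edges[, 2])
    if (any(k %in% names(rel))) stop("edge sets are not pairwise disjoint")
    c(rel, stats::setNames(rep(tag, length(k)), k))
  }
  rel <- add(rel, ldt, "LT"); rel <- add(rel, edt, "EQ"); rel <- add(rel, pdt, "GT")
  n <- length(v)
  if (length(rel) != n * (n - 1) / 2) {
    stop("edge sets do not cover all unordered pairs (", length(rel), " of ",
         n * (n - 1) / 2, ")")
  }
  structure(list(ldt = ldt, edt = edt, pdt = pdt,
                 vertices = v, sigma = ldt$sigma, rel = rel),
            class = "three_partition")
}

#' Build a 3-partition from a relation table
#'
#' @param vertices vertex labels.
#' @param sigma named coloring.
#' @param pairs two-column character matrix of unordered pairs.
#' @param rel character vector (`"LT"`, `"EQ"`, `"GT"`) parallel to `pairs`.
#' @return a `three_partition`.
#' @export
partition_from_rel <- function(vertices, sigma, pairs, rel) {
  pairs <- matrix(as.character(pairs), ncol = 2)
  pick <- function(tag) pairs[rel == tag, , drop = FALSE]
  three_partition(colored_graph(vertices, pick("LT"), sigma),
                  colored_graph(vertices, pick("EQ"), sigma),
                  colored_graph(vertices, pick("GT"), sigma))
}

#' @export
print.three_partition <- function(x, ...) {
  cat("graph 3-partition on", length(x$vertices), "vertices: ",
      nrow(x$ldt$edges), "LDT /", nrow(x$edt$edges), "EDT /",
      nrow(x$pdt$edges), "PDT edges\n")
  invisible(x)
}

#' Relation of a vertex pair in a 3-partition
#' @param g a `three_partition`.
#' @param u,v distinct vertex labels.
#' @return `"LT"`, `"EQ"` or `"GT"`.
#' @export
pair_relation <- function(g, u, v) unname(g$rel[pair_key(u, v)])

#' Restriction of a 3-partition to a vertex subset
#' @param g a `three_partition`.
#' @param vs vertex subset.
#' @return a `three_partition` on `vs`.
#' @export
restrict_partition <- function(g, vs) {
  three_partition(graph_induced(g$ldt, vs), graph_induced(g$edt, vs),
                  graph_induced(g$pdt, vs))
}

#' Rainbow triangles of a 3-partition
#'
#' A rainbow triangle is a vertex triple carrying one edge of each class.
#' Induced P4s in the EDT graph are always accompanied by rainbow triangles.
#'
#' @param g a `three_partition`.
#' @return a character matrix with three columns (one row per triangle).
#' @export
rainbow_triangles <- function(g) {
  v <- g$vertices
  out <- matrix(character(0), ncol = 3)
  if (length(v) < 3) return(out)
  trips <- utils::combn(v, 3)
  hit <- logical(ncol(trips))
  for (j in seq_len(ncol(trips))) {
    t <- trips[, j]
    rels <- c(g$rel[pair_key(t[1], t[2])], g$rel[pair_key(t[1], t[3])],
              g$rel[pair_key(t[2], t[3])])
    hit[j] <- length(unique(rels)) == 3
  }
  t(trips[, hit, drop = FALSE])
}

#' Structural report on a 3-partition
#'
#' Collects the structural invariants that valid divergence-time partitions
#' must satisfy: LDT and PDT graphs are cographs, LDT and EDT graphs are
#' properly colored, the EDT graph has no induced path on six vertices and
#' no odd hole, and every induced P4 in the EDT graph comes with rainbow
#' triangles.  Exhaustive searches are guarded by size limits; above the
#' limit the corresponding field is `NA` and a note is recorded (never a
#' silent truncation).
#'
#' @param g a `three_partition`.
#' @param max_path_n size guard for the induced-path search.
#' @param max_hole_n size guard for the odd-hole search.
#' @return a list with fields `ldt_cograph`, `pdt_cograph`, `edt_cograph`,
#'   `proper_coloring_ldt`, `proper_coloring_edt`, `rainbow_triangles`,
#'   `longest_induced_path_in_edt`, `edt_odd_hole_free`, `notes`.
#' @export
structural_report <- function(g, max_path_n = 14, max_hole_n = 11) {
  stopifnot(inherits(g, "three_partition"))
  notes <- character(0)
  n <- length(g$vertices)
  adj_edt <- graph_adjacency(g$edt)
  lip <- NA_integer_
  if (n <= max_path_n) {
    lip <- longest_induced_path_adj(adj_edt)
  } else {
    notes <- c(notes, sprintf(
      "longest induced path not computed: %d vertices exceeds guard %d",
      n, max_path_n))
  }
  ohf <- NA
  if (n <= max_hole_n) {
    ohf <- !.has_odd_hole(adj_edt)
  } else {
    notes <- c(notes, sprintf(
      "odd-hole search not computed: %d vertices exceeds guard %d",
      n, max_hole_n))
  }
  list(ldt_cograph = isTRUE(is_cograph(g$ldt)),
       pdt_cograph = isTRUE(is_cograph(g$pdt)),
       edt_cograph = isTRUE(is_cograph(g$edt)),
       proper_coloring_ldt = is_properly_colored(g$ldt),
       proper_coloring_edt = is_properly_colored(g$edt),
       rainbow_triangles = rainbow_triangles(g),
       longest_induced_path_in_edt = lip,
       edt_odd_hole_free = ohf,
       notes = notes)
}

#' Is a graph complete multipartite?
#'
#' Equivalent to the complement being a disjoint union of cliques.  The
#' symmetrized Fitch graph of every scenario has this shape.
#'
#' @param g a `colored_graph`.
#' @return logical scalar.
#' @export
is_complete_multipartite <- function(g) {
  adj <- graph_adjacency(g)
  co <- !adj
  diag(co) <- FALSE
  comps <- adj_components(co)
  for (c in comps) {
    sub <- co[c, c, drop = FALSE]
    diag(sub) <- TRUE
    if (!all(sub)) return(FALSE)
  }
  TRUE
}
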