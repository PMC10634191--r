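# Planted phylogenetic trees.
#
# All trees in this package are *planted*: an extra degree-1 root (label "0"
# by default) sits above the conventional root rho.  Every other non-leaf
# vertex has >= 2 children.  Vertices are addressed by unique character
# labels; leaf labels are user data, internal labels are synthetic
# ("v<preorder index>") unless explicitly supplied.

#' Construct a planted tree from parent pointers
#'
#' Low-level constructor.  `parent` is a named character vector mapping each
#' vertex label to its parent label; exactly one vertex (the planted root)
#' maps to `NA`.  `children_order` optionally fixes the child order per
#' vertex; by default children appear in the order they occur in `parent`.
#'
#' @param parent named character vector (`NA` for the planted root).
#' @param children_order optional named list of character vectors.
#' @return an object of class `planted_tree`.
#' @export
planted_tree <- function(parent, children_order = NULL) {
  labels <- names(parent)
  if (is.null(labels) || anyDuplicated(labels) > 0 || any(!nzchar(labels))) {
    stop("vertex labels must be unique non-empty strings")
  }
  n <- length(labels)
  idx <- seq_len(n)
  names(idx) <- labels
  par <- rep(NA_integer_, n)
  for (i in idx) {
    p <- parent[[i]]
    if (!is.na(p)) {
      j <- idx[[p]]
      if (is.null(j) || is.na(j)) stop("unknown parent label: ", p)
      par[i] <- j
    }
  }
  roots <- which(is.na(par))
  if (length(roots) != 1L) stop("exactly one vertex must have no parent")
  children <- vector("list", n)
  for (i in idx) children[[i]] <- integer(0)
  for (i in idx) if (!is.na(par[i])) children[[par[i]]] <- c(children[[par[i]]], i)
  if (!is.null(children_order)) {
    for (lab in names(children_order)) {
      i <- idx[[lab]]
      want <- idx[children_order[[lab]]]
      if (length(want) != length(children[[i]]) || !setequal(want, children[[i]])) {
        stop("children_order inconsistent at vertex ", lab)
      }
      children[[i]] <- as.integer(want)
    }
  }
  new_planted_tree(labels, par, children, roots)
}

new_planted_tree <- function(labels, parent, children, planted_root) {
  n <- length(labels)
  n_child <- lengths(children)
  is_leaf <- n_child == 0L
  if (n_child[planted_root] != 1L) {
    if (!(n == 1L && is_leaf[planted_root])) {
      stop("planted root must have exactly one child")
    }
  }
  bad <- which(!is_leaf & n_child < 2L & seq_len(n) != planted_root)
  if (length(bad) > 0) {
    stop("non-root vertex with a single child: ", labels[bad[1]])
  }
  # acyclicity / connectivity: count reachable from planted root
  seen <- logical(n)
  stack <- planted_root
  while (length(stack) > 0) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    if (seen[v]) stop("cycle detected in parent relation")
    seen[v] <- TRUE
    stack <- c(stack, children[[v]])
  }
  if (!all(seen)) stop("parent relation does not connect all vertices")
  root <- if (n_child[planted_root] == 1L) children[[planted_root]][1] else planted_root
  structure(
    list(labels = labels, parent = parent, children = children,
         planted_root = planted_root, root = root, is_leaf = is_leaf),
    class = "planted_tree")
}

#' @export
print.planted_tree <- function(x, ...) {
  cat("planted tree with", sum(x$is_leaf), "leaves:", write_newick(x), "\n")
  invisible(x)
}

v_index <- function(tree, label) {
  i <- match(label, tree$labels)
  if (anyNA(i)) stop("unknown vertex label(s): ",
                     paste(label[is.na(i)], collapse = ", "))
  i
}

#' Leaf labels of a tree
#' @param tree a `planted_tree`.
#' @return character vector of leaf labels.
#' @export
tree_leaves <- function(tree) tree$labels[tree$is_leaf]

#' All vertex labels of a tree
#' @param tree a `planted_tree`.
#' @return character vector of all labels (planted root included).
#' @export
tree_vertices <- function(tree) tree$labels

#' Inner vertex labels (excluding leaves and the planted root)
#' @param tree a `planted_tree`.
#' @return character vector.
#' @export
tree_inner <- function(tree) {
  keep <- !tree$is_leaf & seq_along(tree$labels) != tree$planted_root
  tree$labels[keep]
}

# path of indices from v up to the planted root (inclusive)
.anc_path <- function(tree, i) {
  out <- i
  while (!is.na(tree$parent[i])) {
    i <- tree$parent[i]
    out <- c(out, i)
  }
  out
}

# TRUE iff a is (weakly) below b, indices
.below <- function(tree, a, b) {
  while (!is.na(a)) {
    if (a == b) return(TRUE)
    a <- tree$parent[a]
  }
  FALSE
}

#' Last common ancestor of a set of leaves (or vertices)
#'
#' Returns the unique minimal vertex lying above every element of `A`.
#'
#' @param tree a `planted_tree`.
#' @param A character vector of leaf labels (non-empty).
#' @return the label of the last common ancestor.
#' @export
tree_lca <- function(tree, A) {
  if (length(A) == 0) stop("lca of an empty set is undefined")
  ii <- v_index(tree, A)
  path <- .anc_path(tree, ii[1])
  for (j in ii[-1]) {
    inpath <- match(.anc_path(tree, j), path)
    first <- suppressWarnings(min(inpath, na.rm = TRUE))
    path <- path[first:length(path)]
  }
  tree$labels[path[1]]
}

# depth (edges from planted root); used for ordering
.depths <- function(tree) {
  n <- length(tree$labels)
  d <- rep(NA_integer_, n)
  d[tree$planted_root] <- 0L
  stack <- tree$planted_root
  while (length(stack) > 0) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    for (c in tree$children[[v]]) {
      d[c] <- d[v] + 1L
      stack <- c(stack, c)
    }
  }
  d
}

# leaf sets below every vertex, list of character vectors
.subtree_leaves <- function(tree) {
  n <- length(tree$labels)
  out <- vector("list", n)
  ord <- .postorder(tree)
  for (v in ord) {
    if (tree$is_leaf[v]) out[[v]] <- tree$labels[v]
    else out[[v]] <- unlist(lapply(tree$children[[v]], function(c) out[[c]]))
  }
  out
}

.postorder <- function(tree) {
  s1 <- tree$planted_root; s2 <- integer(0)
  while (length(s1) > 0) {
    v <- s1[length(s1)]; s1 <- s1[-length(s1)]
    s2 <- c(s2, v)
    s1 <- c(s1, tree$children[[v]])
  }
  rev(s2)
}

.preorder <- function(tree) {
  out <- integer(0)
  stack <- tree$planted_root
  while (length(stack) > 0) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    out <- c(out, v)
    stack <- c(stack, rev(tree$children[[v]]))
  }
  out
}

#' Restriction of a tree to a leaf subset
#'
#' Computes the minimal subtree connecting `leaves` and suppresses all
#' resulting degree-two vertices.  Surviving internal vertices keep their
#' labels; a fresh planted root (handle) is placed above the restriction's
#' root so that the result is again a `planted_tree`.
#'
#' @param tree a `planted_tree`.
#' @param leaves non-empty character vector, a subset of `tree_leaves(tree)`.
#' @return a `planted_tree` with leaf set `leaves`.
#' @export
tree_restrict <- function(tree, leaves) {
  if (length(leaves) == 0) stop("restriction to an empty leaf set")
  ii <- v_index(tree, leaves)
  if (!all(tree$is_leaf[ii])) {
    stop("restriction set contains non-leaves: ",
         paste(leaves[!tree$is_leaf[ii]], collapse = ", "))
  }
  top <- v_index(tree, tree_lca(tree, leaves))
  keepset <- leaves
  rec <- function(v) {
    # returns label of the vertex representing v in the restriction, or NULL
    if (tree$is_leaf[v]) {
      if (tree$labels[v] %in% keepset) return(tree$labels[v]) else return(NULL)
    }
    subs <- list()
    for (c in tree$children[[v]]) {
      r <- rec(c)
      if (!is.null(r)) subs[[length(subs) + 1L]] <- r
    }
    if (length(subs) == 0) return(NULL)
    if (length(subs) == 1) return(subs[[1]])
    list(label = tree$labels[v], children = subs)
  }
  nested <- rec(top)
  tree_from_nested(nested, keep_labels = TRUE)
}

# Build a planted_tree from a nested structure: a leaf is a character scalar,
# an inner vertex is either list(label=, children=list(...)) or an unnamed
# list of children.  Internal vertices without labels get "v<preorder>".
tree_from_nested <- function(nested, keep_labels = FALSE, planted_label = "0") {
  labs <- character(0); pars <- character(0)
  used <- new.env(parent = emptyenv())
  collect_used <- function(x) {
    if (is.character(x)) assign(x, TRUE, envir = used)
    else {
      if (!is.null(x$label)) assign(x$label, TRUE, envir = used)
      kids <- if (!is.null(x$children)) x$children else x
      for (k in kids) collect_used(k)
    }
  }
  collect_used(nested)
  counter <- 0L
  fresh <- function(pref) {
    repeat {
      counter <<- counter + 1L
      cand <- paste0(pref, counter)
      if (!exists(cand, envir = used)) {
        assign(cand, TRUE, envir = used)
        return(cand)
      }
    }
  }
  pl <- planted_label
  while (exists(pl, envir = used)) pl <- paste0(pl, "_")
  labs <- pl; pars <- NA_character_
  add <- function(x, parent_lab) {
    if (is.character(x)) {
      labs <<- c(labs, x); pars <<- c(pars, parent_lab)
      return(invisible(NULL))
    }
    lab <- if (keep_labels && !is.null(x$label)) x$label else fresh("v")
    labs <<- c(labs, lab); pars <<- c(pars, parent_lab)
    kids <- if (!is.null(x$children)) x$children else x
    for (k in kids) add(k, lab)
  }
  add(nested, pl)
  p <- pars; names(p) <- labs
  planted_tree(p)
}

#' Rooted and fan triples
#'
#' `rooted_triple(x, y, z)` denotes the triple xy|z (the pair `{x, y}`
#' diverged after splitting from the outgroup `z`); `fan_triple(x, y, z)` is
#' the star on the three leaves.
#'
#' @param x,y,z pairwise distinct leaf labels.
#' @return an object of class `edt_triple`.
#' @export
rooted_triple <- function(x, y, z) {
  if (anyDuplicated(c(x, y, z)) > 0) stop("triple leaves must be distinct")
  p <- sort(c(x, y), method = "radix")
  structure(list(type = "rooted", a = p[1], b = p[2], out = z),
            class = "edt_triple")
}

#' @rdname rooted_triple
#' @export
fan_triple <- function(x, y, z) {
  if (anyDuplicated(c(x, y, z)) > 0) stop("triple leaves must be distinct")
  m <- sort(c(x, y, z), method = "radix")
  structure(list(type = "fan", members = m), class = "edt_triple")
}

#' @export
print.edt_triple <- function(x, ...) {
  if (x$type == "rooted") cat(x$a, ",", x$b, "|", x$out, "\n", sep = "")
  else cat(paste(x$members, collapse = "|"), "\n")
  invisible(x)
}

#' Does a tree display a triple?
#'
#' A tree displays the rooted triple xy|z when lca(x,y) lies strictly below
#' lca(x,z) = lca(y,z); it displays the fan triple x|y|z when all three
#' pairwise last common ancestors coincide.
#'
#' @param tree a `planted_tree`.
#' @param trip an `edt_triple` (see [rooted_triple()]).
#' @return logical scalar.
#' @export
tree_displays <- function(tree, trip) {
  stopifnot(inherits(trip, "edt_triple"))
  if (trip$type == "rooted") {
    .displays_rt(tree, trip$a, trip$b, trip$out)
  } else {
    m <- trip$members
    l12 <- tree_lca(tree, m[1:2])
    l13 <- tree_lca(tree, m[c(1, 3)])
    l23 <- tree_lca(tree, m[2:3])
    l12 == l13 && l13 == l23
  }
}

.displays_rt <- function(tree, x, y, z) {
  lxy <- v_index(tree, tree_lca(tree, c(x, y)))
  lxz <- v_index(tree, tree_lca(tree, c(x, z)))
  lxy != lxz && .below(tree, lxy, lxz)
}

#' Canonical topology string of a tree
#'
#' Internal labels and the planted handle are ignored; children are sorted,
#' so two trees are isomorphic as leaf-labelled rooted trees precisely when
#' their canonical strings agree.
#'
#' @param tree a `planted_tree`.
#' @return a character scalar.
#' @export
tree_canonical <- function(tree) {
  rec <- function(v) {
    if (tree$is_leaf[v]) return(tree$labels[v])
    parts <- vapply(tree$children[[v]], rec, character(1))
    paste0("(", paste(sort(parts, method = "radix"), collapse = ","), ")")
  }
  rec(tree$root)
}

#' Is the (unplanted part of the) tree binary?
#' @param tree a `planted_tree`.
#' @return logical scalar.
#' @export
is_binary_tree <- function(tree) {
  n_child <- lengths(tree$children)
  inner <- !tree$is_leaf & seq_along(tree$labels) != tree$planted_root
  all(n_child[inner] == 2L)
}

#' Construct a time map for a dated tree
#'
#' Leaves receive `leaf_times` (a single value or a named vector over the
#' leaf labels); every internal vertex v, including the planted root, is
#' stamped `max(leaf_times) + scale * height(v)` where height counts edges to
#' the farthest descendant leaf.  The result is strictly decreasing along
#' every edge.  The defaults (`leaf_times = 0`, `scale = 3`) stamp the
#' two-species tree (A,B) with leaves at 0, the root at 3 and the planted
#' root at 6.
#'
#' @param tree a `planted_tree`.
#' @param leaf_times numeric scalar or named numeric over leaf labels.
#' @param scale positive numeric, time units per height level.
#' @return a named numeric vector over all vertex labels.
#' @export
assign_time_map <- function(tree, leaf_times = 0, scale = 3) {
  stopifnot(scale > 0)
  leaves <- tree_leaves(tree)
  if (length(leaf_times) == 1 && is.null(names(leaf_times))) {
    lt <- stats::setNames(rep(as.numeric(leaf_times), length(leaves)), leaves)
  } else {
    if (!all(leaves %in% names(leaf_times))) stop("leaf_times must cover all leaves")
    lt <- leaf_times[leaves]
  }
  n <- length(tree$labels)
  height <- integer(n)
  for (v in .postorder(tree)) {
    if (!tree$is_leaf[v]) {
      height[v] <- 1L + max(height[tree$children[[v]]])
    }
  }
  base <- max(lt)
  tau <- numeric(n)
  for (v in seq_len(n)) {
    tau[v] <- if (tree$is_leaf[v]) lt[[tree$labels[v]]] else base + scale * height[v]
  }
  names(tau) <- tree$labels
  check_time_map(tree, tau)
  tau
}

#' Verify that a vertex stamping is a valid time map
#'
#' Checks the defining property: stamps strictly decrease from every vertex
#' to each of its children.
#'
#' @param tree a `planted_tree`.
#' @param tau named numeric vector over all vertex labels.
#' @return invisibly `TRUE`; stops with an informative error otherwise.
#' @export
check_time_map <- function(tree, tau) {
  if (!all(tree$labels %in% names(tau))) stop("time map must cover all vertices")
  for (v in seq_along(tree$labels)) {
    for (c in tree$children[[v]]) {
      if (!(tau[[tree$labels[c]]] < tau[[tree$labels[v]]])) {
        stop("time map not strictly decreasing on edge ",
             tree$labels[v], " -> ", tree$labels[c])
      }
    }
  }
  invisible(TRUE)
}

#' Read a rooted (multifurcating) Newick string as a planted tree
#'
#' A planted root is added above the Newick root.  By default internal
#' Newick labels are discarded and replaced by deterministic synthetic
#' labels in preorder ("v1", "v2", ...); with `keep_internal_ids = TRUE` the
#' internal labels in the string are kept (they must then be present and
#' unique), which is how scenario bundles serialize reconciliation keys.
#' Branch lengths, if present, are ignored: dating lives in time maps.
#'
#' @param text a Newick string (single tree).
#' @param keep_internal_ids keep internal labels from the string?
#' @return a `planted_tree`.
#' @export
read_newick <- function(text, keep_internal_ids = FALSE) {
  text <- trimws(text)
  if (!nzchar(text)) stop("Newick parse error at position 1: empty string")
  .newick_check_balance(text)
  # single-leaf tree: no parentheses/commas
  if (!grepl("[(),]", text)) {
    lab <- sub(";\\s*$", "", text)
    lab <- sub(":[0-9eE+.-]+$", "", lab)
    p <- c(NA_character_, "0")
    names(p) <- c("0", lab)
    if (lab == "0") stop("leaf label '0' collides with the planted root label")
    return(planted_tree(p))
  }
  if (!grepl(";\\s*$", text)) text <- paste0(text, ";")
  phy <- tryCatch(ape::read.tree(text = text),
                  error = function(e) NULL, warning = function(w) NULL)
  if (is.null(phy)) stop("Newick parse error: unreadable tree string")
  ntip <- length(phy$tip.label)
  if (anyDuplicated(phy$tip.label) > 0) stop("duplicate leaf labels in Newick string")
  nnode <- phy$Nnode
  total <- ntip + nnode
  labs <- character(total)
  labs[seq_len(ntip)] <- phy$tip.label
  if (keep_internal_ids) {
    if (is.null(phy$node.label) || any(!nzchar(phy$node.label))) {
      stop("keep_internal_ids = TRUE requires labels on all internal vertices")
    }
    labs[ntip + seq_len(nnode)] <- phy$node.label
  } else {
    labs[ntip + seq_len(nnode)] <- paste0(".n", seq_len(nnode))  # placeholder
  }
  parent <- rep(NA_character_, total)
  kids <- vector("list", total)
  for (i in seq_len(total)) kids[[i]] <- integer(0)
  for (r in seq_len(nrow(phy$edge))) {
    p <- phy$edge[r, 1]; c <- phy$edge[r, 2]
    parent[c] <- labs[p]
    kids[[p]] <- c(kids[[p]], c)
  }
  if (!keep_internal_ids) {
    # relabel internals by preorder over the phylo structure
    rootn <- ntip + 1L
    cnt <- 0L
    stack <- rootn
    while (length(stack) > 0) {
      v <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (v > ntip) {
        cnt <- cnt + 1L
        newlab <- paste0("v", cnt)
        old <- labs[v]
        labs[v] <- newlab
        parent[!is.na(parent) & parent == old] <- newlab
        stack <- c(stack, rev(kids[[v]]))
      }
    }
  }
  if (anyDuplicated(labs) > 0) stop("duplicate vertex labels in Newick string")
  planted <- "0"
  while (planted %in% labs) planted <- paste0(planted, "_")
  rootlab <- labs[ntip + 1L]
  all_labs <- c(planted, labs)
  p <- c(NA_character_, parent)
  p[match(rootlab, all_labs)] <- planted
  names(p) <- all_labs
  ord <- lapply(kids, function(k) labs[k])
  names(ord) <- labs
  ord <- ord[lengths(ord) > 0]
  planted_tree(p, children_order = ord)
}

.newick_check_balance <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0) stop("Newick parse error at position ", i,
                          ": unmatched ')'")
    }
  }
  if (depth != 0) stop("Newick parse error at position ", nchar(text),
                       ": ", depth, " unclosed '('")
  invisible(TRUE)
}

#' Write a planted tree as a Newick string
#'
#' The planted root is omitted.  With `internal_ids = TRUE` internal vertex
#' labels are written (as needed to serialize scenarios losslessly).
#'
#' @param tree a `planted_tree`.
#' @param internal_ids write internal labels?
#' @return a Newick string ending in ";".
#' @export
write_newick <- function(tree, internal_ids = FALSE) {
  rec <- function(v) {
    if (tree$is_leaf[v]) return(tree$labels[v])
    inner <- paste(vapply(tree$children[[v]], rec, character(1)), collapse = ",")
    paste0("(", inner, ")", if (internal_ids) tree$labels[v] else "")
  }
  paste0(rec(tree$root), ";")
}
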