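# Informative and forbidden rooted triples, BUILD, and construction of trees
# that display required triples while avoiding forbidden ones.

# triple tables: data frames with columns a, b (sorted pair) and out.
triple_df <- function(a = character(0), b = character(0), out = character(0)) {
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  df <- data.frame(a = a, b = b, out = out)
  df <- unique(df)
  df[order(df$a, df$b, df$out, method = "radix"), , drop = FALSE]
}

triple_keys <- function(df) paste(df$a, df$b, df$out, sep = "\r")

#' A system of required and forbidden rooted triples
#'
#' @param required,forbidden data frames with columns `a`, `b`, `out`
#'   (each row the triple ab|out), e.g. built with [rooted_triple()] rows.
#' @param labels the full label universe the system lives on.
#' @return an object of class `triple_system`.
#' @export
triple_system <- function(required, forbidden, labels) {
  required <- triple_df(required$a, required$b, required$out)
  forbidden <- triple_df(forbidden$a, forbidden$b, forbidden$out)
  labels <- sort(unique(as.character(labels)), method = "radix")
  used <- unique(c(required$a, required$b, required$out,
                   forbidden$a, forbidden$b, forbidden$out))
  if (!all(used %in% labels)) stop("triples mention labels outside the universe")
  structure(list(required = required, forbidden = forbidden, labels = labels),
            class = "triple_system")
}

#' @export
print.triple_system <- function(x, ...) {
  cat("triple system on", length(x$labels), "labels:",
      nrow(x$required), "required,", nrow(x$forbidden), "forbidden\n")
  invisible(x)
}

#' Informative and forbidden gene-tree triples of a 3-partition
#'
#' Required: xy|z when xy is an LDT edge but xz, yz are not, or when xz and
#' yz are PDT edges but xy is not.  Forbidden: xz|y and yz|x when xz and yz
#' are EDT edges but xy is not.  Any gene tree of an explaining scenario
#' displays all required triples and none of the forbidden ones.
#'
#' @param g a `three_partition`.
#' @return a `triple_system` over the partition's vertices.
#' @export
gene_triples <- function(g) {
  v <- g$vertices
  ra <- rb <- ro <- fa <- fb <- fo <- character(0)
  if (length(v) >= 3) {
    trips <- utils::combn(v, 3)
    for (j in seq_len(ncol(trips))) {
      t <- trips[, j]
      for (k in 1:3) {
        z <- t[k]; xy <- t[-k]
        x <- xy[1]; y <- xy[2]
        rxy <- g$rel[[pair_key(x, y)]]
        rxz <- g$rel[[pair_key(x, z)]]
        ryz <- g$rel[[pair_key(y, z)]]
        if ((rxy == "LT" && rxz != "LT" && ryz != "LT") ||
            (rxz == "GT" && ryz == "GT" && rxy != "GT")) {
          ra <- c(ra, x); rb <- c(rb, y); ro <- c(ro, z)
        }
        if (rxz == "EQ" && ryz == "EQ" && rxy != "EQ") {
          fa <- c(fa, x, y); fb <- c(fb, z, z); fo <- c(fo, y, x)
        }
      }
    }
  }
  triple_system(triple_df(ra, rb, ro), triple_df(fa, fb, fo), v)
}

#' Informative and forbidden species-tree triples of a 3-partition
#'
#' Triples live on the colors.  Required: sigma(x)sigma(y)|sigma(z) when
#' (a') xz and yz are LDT edges but xy is not, or (b') xy is a PDT edge but
#' xz, yz are not; forbidden: sigma(x)sigma(z)|sigma(y) and its mirror when
#' xz, yz are EDT edges but xy is not.  Only triples of pairwise distinct
#' colors are informative.
#'
#' @param g a `three_partition`.
#' @return a `triple_system` over the colors appearing in `g`.
#' @export
species_triples <- function(g) {
  v <- g$vertices
  colors <- sort(unique(unname(g$sigma)), method = "radix")
  ra <- rb <- ro <- fa <- fb <- fo <- character(0)
  if (length(v) >= 3) {
    trips <- utils::combn(v, 3)
    for (j in seq_len(ncol(trips))) {
      t <- trips[, j]
      if (length(unique(g$sigma[t])) < 3) next
      for (k in 1:3) {
        z <- t[k]; xy <- t[-k]
        x <- xy[1]; y <- xy[2]
        X <- g$sigma[[x]]; Y <- g$sigma[[y]]; Z <- g$sigma[[z]]
        rxy <- g$rel[[pair_key(x, y)]]
        rxz <- g$rel[[pair_key(x, z)]]
        ryz <- g$rel[[pair_key(y, z)]]
        if ((rxz == "LT" && ryz == "LT" && rxy != "LT") ||
            (rxy == "GT" && rxz != "GT" && ryz != "GT")) {
          ra <- c(ra, X); rb <- c(rb, Y); ro <- c(ro, Z)
        }
        if (rxz == "EQ" && ryz == "EQ" && rxy != "EQ") {
          fa <- c(fa, X, Y); fb <- c(fb, Z, Z); fo <- c(fo, Y, X)
        }
      }
    }
  }
  triple_system(triple_df(ra, rb, ro), triple_df(fa, fb, fo), colors)
}

#' Does a tree agree with a triple system?
#'
#' TRUE when the tree displays every required triple and none of the
#' forbidden ones.
#'
#' @param tree a `planted_tree` whose leaves cover the system's labels.
#' @param sys a `triple_system`.
#' @return logical scalar.
#' @export
agrees <- function(tree, sys) {
  req <- sys$required
  for (r in seq_len(nrow(req))) {
    if (!.displays_rt(tree, req$a[r], req$b[r], req$out[r])) return(FALSE)
  }
  forb <- sys$forbidden
  for (r in seq_len(nrow(forb))) {
    if (.displays_rt(tree, forb$a[r], forb$b[r], forb$out[r])) return(FALSE)
  }
  TRUE
}

# Aho graph components: edges a-b for every triple ab|z with all of a, b, z
# inside `labels`; returns list of character vectors (components)
.aho_components <- function(required, labels) {
  n <- length(labels)
  adj <- matrix(FALSE, n, n, dimnames = list(labels, labels))
  keep <- required$a %in% labels & required$b %in% labels & required$out %in% labels
  req <- required[keep, , drop = FALSE]
  if (nrow(req) > 0) {
    adj[cbind(req$a, req$b)] <- TRUE
    adj[cbind(req$b, req$a)] <- TRUE
  }
  comps <- adj_components(adj)
  lapply(comps, function(i) labels[i])
}

order_blocks <- function(blocks) {
  blocks <- lapply(blocks, function(b) sort(b, method = "radix"))
  blocks[order(vapply(blocks, `[`, character(1), 1), method = "radix")]
}

#' BUILD: a tree displaying a set of required triples
#'
#' The classic recursion on the Aho graph: components of the graph joining
#' the cherry of every triple become the children of the current node; a
#' single component on two or more labels certifies inconsistency.
#'
#' @param required a data frame of triples (`a`, `b`, `out`) or a
#'   `triple_system` (whose forbidden set is ignored).
#' @param labels label universe for the tree's leaves.
#' @return a `planted_tree` displaying all triples, or `NULL` when the set is
#'   inconsistent.
#' @export
aho_build <- function(required, labels) {
  if (inherits(required, "triple_system")) required <- required$required
  required <- triple_df(required$a, required$b, required$out)
  labels <- sort(unique(as.character(labels)), method = "radix")
  rec <- function(labs) {
    if (length(labs) == 1) return(labs)
    comps <- order_blocks(.aho_components(required, labs))
    if (length(comps) == 1) return(NULL)
    subs <- lapply(comps, rec)
    if (any(vapply(subs, is.null, logical(1)))) return(NULL)
    subs
  }
  nested <- rec(labels)
  if (is.null(nested)) return(NULL)
  if (is.character(nested) && length(labels) == 1) {
    return(tree_from_nested(nested))
  }
  tree_from_nested(nested)
}

#' A tree displaying required triples and avoiding forbidden ones
#'
#' Top-down recursion in the style of the mixed-triplets-on-trees algorithm:
#' the children blocks of the current node start from the Aho-graph
#' components of the required triples and are then merged to a least fixed
#' point under the rule "if x and z share a block and xz|y is forbidden, y
#' must join that block" (otherwise the forbidden triple would be displayed).
#' If everything collapses into a single block no agreeing tree exists;
#' otherwise each block is solved recursively.  Merging is performed in
#' lexicographic order of block representatives, so the output is
#' deterministic; any tree that agrees with the system is acceptable
#' downstream.
#'
#' @param required,forbidden triple data frames (`a`, `b`, `out`).
#' @param labels label universe.
#' @return a `planted_tree` agreeing with `(required, forbidden)`, or `NULL`
#'   when none exists.  The returned tree may be non-binary.
#' @export
mixed_tree <- function(required, forbidden, labels) {
  required <- triple_df(required$a, required$b, required$out)
  forbidden <- triple_df(forbidden$a, forbidden$b, forbidden$out)
  labels <- sort(unique(as.character(labels)), method = "radix")
  rec <- function(labs) {
    if (length(labs) == 1) return(labs)
    blocks <- order_blocks(.aho_components(required, labs))
    keep <- forbidden$a %in% labs & forbidden$b %in% labs & forbidden$out %in% labs
    forb <- forbidden[keep, , drop = FALSE]
    block_of <- integer(0)
    assign_blocks <- function(blocks) {
      bo <- integer(length(labs)); names(bo) <- labs
      for (i in seq_along(blocks)) bo[blocks[[i]]] <- i
      bo
    }
    repeat {
      block_of <- assign_blocks(blocks)
      merged <- FALSE
      for (r in seq_len(nrow(forb))) {
        bi <- block_of[[forb$a[r]]]; bj <- block_of[[forb$b[r]]]
        by <- block_of[[forb$out[r]]]
        if (bi == bj && by != bi) {
          blocks[[bi]] <- sort(c(blocks[[bi]], blocks[[by]]), method = "radix")
          blocks[[by]] <- NULL
          blocks <- order_blocks(blocks)
          merged <- TRUE
          break
        }
      }
      if (!merged) break
    }
    if (length(blocks) == 1) return(NULL)
    subs <- lapply(blocks, rec)
    if (any(vapply(subs, is.null, logical(1)))) return(NULL)
    subs
  }
  nested <- rec(labels)
  if (is.null(nested)) return(NULL)
  tree_from_nested(nested)
}

#' Tree that agrees with a triple system, or NULL
#' @param sys a `triple_system`.
#' @return a `planted_tree` or `NULL`.
#' @export
agreeing_tree <- function(sys) mixed_tree(sys$required, sys$forbidden, sys$labels)

#' Enumerate all rooted phylogenetic trees on a label set
#'
#' Every rooted multifurcating tree with the given leaves is produced exactly
#' once (as a `planted_tree`).  Intended as a small-instance oracle; the
#' count grows super-exponentially, so `labels` is limited to 7 elements.
#'
#' @param labels character vector (2 to 7 labels).
#' @return a list of `planted_tree`s.
#' @export
enumerate_rooted_trees <- function(labels) {
  labels <- sort(unique(as.character(labels)), method = "radix")
  if (length(labels) < 1 || length(labels) > 7) {
    stop("enumeration supported for 1 to 7 labels")
  }
  rec <- function(labs) {
    if (length(labs) == 1) return(list(labs[1]))
    out <- list()
    for (p in .set_partitions(labs)) {
      if (length(p) < 2) next
      child_options <- lapply(p, rec)
      grid <- .cartesian(child_options)
      for (combo in grid) out[[length(out) + 1L]] <- combo
    }
    out
  }
  lapply(rec(labels), tree_from_nested)
}

# all set partitions of labs (list of lists of character vectors), via
# restricted growth strings
.set_partitions <- function(labs) {
  n <- length(labs)
  out <- list()
  a <- integer(n)
  recurse <- function(i, maxb) {
    if (i > n) {
      k <- maxb
      blocks <- vector("list", k)
      for (b in seq_len(k)) blocks[[b]] <- labs[a[seq_len(n)] == b]
      out[[length(out) + 1L]] <<- blocks
      return(invisible(NULL))
    }
    for (b in seq_len(maxb + 1L)) {
      a[i] <<- b
      recurse(i + 1L, max(maxb, b))
    }
  }
  recurse(1L, 0L)
  out
}

.cartesian <- function(lists) {
  # lists: list of lists; returns list of lists (one pick per slot)
  out <- list(list())
  for (slot in lists) {
    nxt <- list()
    for (partial in out) {
      for (item in slot) {
        nxt[[length(nxt) + 1L]] <- c(partial, list(item))
      }
    }
    out <- nxt
  }
  out
}
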