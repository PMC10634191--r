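# Construction of explaining scenarios from a valid graph 3-partition.
#
# The gene tree is grown top-down by a recursion over subsets L' of genes and
# a current species vertex u_S, guided by three nested auxiliary graphs on
# L': connected components of H1 become children mapped onto u_S itself,
# components of H2 become children mapped just below u_S, and components of
# H3 are recursed into a child of u_S.  A restricted variant constrains one
# otherwise free choice so that the result is additionally fully witnessed
# with properly anchored speciation vertices.

#' Validity of a 3-partition as builder input
#'
#' A 3-partition is explainable by a relaxed scenario precisely when the LDT
#' and EDT graphs are properly colored, the LDT and PDT graphs are cographs,
#' and the species triple system extracted from the partition is consistent.
#' Conditions are evaluated in this order and the first failure is reported.
#'
#' @param g a `three_partition`.
#' @return a list with `explainable` (logical), `failed_condition` (`NULL` or
#'   one of `"proper_coloring_ldt"`, `"proper_coloring_edt"`, `"cograph_ldt"`,
#'   `"cograph_pdt"`, `"triples_inconsistent"`), and `species_tree` (an
#'   agreeing species tree when explainable).
#' @export
is_valid_input <- function(g) {
  stopifnot(inherits(g, "three_partition"))  # partition totality checked there
  fail <- function(cond) list(explainable = FALSE, failed_condition = cond,
                              species_tree = NULL)
  if (!is_properly_colored(g$ldt)) return(fail("proper_coloring_ldt"))
  if (!is_properly_colored(g$edt)) return(fail("proper_coloring_edt"))
  if (!isTRUE(is_cograph(g$ldt))) return(fail("cograph_ldt"))
  if (!isTRUE(is_cograph(g$pdt))) return(fail("cograph_pdt"))
  sys <- species_triples(g)
  S <- agreeing_tree(sys)
  if (is.null(S)) return(fail("triples_inconsistent"))
  list(explainable = TRUE, failed_condition = NULL, species_tree = S)
}

#' Safety margin for nested time stamps
#'
#' One third of the minimum edge duration of the dated species tree
#' (including the planted edge).  Stamps placed at `tau_S(u) + eps` and
#' `tau_S(u) - eps` then stay strictly inside the adjacent edges, so the
#' constructed scenario is time consistent.
#'
#' @param S a `planted_tree`.
#' @param tau_S a time map for `S`.
#' @return a positive numeric scalar.
#' @export
epsilon_margin <- function(S, tau_S) {
  check_time_map(S, tau_S)
  dmin <- Inf
  for (v in seq_along(S$labels)) {
    p <- S$parent[v]
    if (is.na(p)) next
    dmin <- min(dmin, tau_S[[S$labels[p]]] - tau_S[[S$labels[v]]])
  }
  if (!is.finite(dmin) || dmin <= 0) stop("degenerate species edge duration")
  dmin / 3
}

#' Auxiliary graphs of the builder recursion
#'
#' On a gene subset `Lp` whose colors all lie below the species vertex `uS`:
#' H1 joins LDT and EDT pairs; H2 keeps the LDT pairs plus the EDT pairs
#' whose colors sit below a common child of `uS`; H3 joins any two genes of
#' one H2 component whose colors sit below a common child.  Components of H3
#' are cliques, and the component partitions refine each other (H3 within H2
#' within H1).
#'
#' @param g a `three_partition`.
#' @param Lp a subset of the partition's vertices.
#' @param uS label of an inner vertex of `S`.
#' @param S the species tree (a `planted_tree`).
#' @return a list with component lists `comps1`, `comps2`, `comps3` (each a
#'   list of sorted character vectors, ordered by smallest member) and edge
#'   key sets `h1_keys`, `h2_keys`.
#' @export
auxiliary_graphs <- function(g, Lp, uS, S) {
  Lp <- sort(as.character(Lp), method = "radix")
  sub_leaves <- .subtree_leaves(S)[[v_index(S, uS)]]
  if (!all(g$sigma[Lp] %in% sub_leaves)) {
    stop("internal error: colors of L' not below u_S (recursion invariant broken)")
  }
  n <- length(Lp)
  below_common_child <- function(x, y) {
    # lca_S(sigma x, sigma y) strictly below uS  <=>  both colors below one child
    tree_lca(S, c(g$sigma[[x]], g$sigma[[y]])) != uS
  }
  a1 <- matrix(FALSE, n, n, dimnames = list(Lp, Lp))
  a2 <- a1
  if (n >= 2) {
    prs <- utils::combn(Lp, 2)
    for (j in seq_len(ncol(prs))) {
      x <- prs[1, j]; y <- prs[2, j]
      r <- g$rel[[pair_key(x, y)]]
      if (r == "LT") {
        a1[x, y] <- a1[y, x] <- TRUE
        a2[x, y] <- a2[y, x] <- TRUE
      } else if (r == "EQ") {
        a1[x, y] <- a1[y, x] <- TRUE
        if (below_common_child(x, y)) a2[x, y] <- a2[y, x] <- TRUE
      }
    }
  }
  comps1 <- lapply(adj_components(a1), function(i) Lp[i])
  comps2 <- lapply(adj_components(a2), function(i) Lp[i])
  # H3: same H2 component and colors below a common child of uS
  a3 <- matrix(FALSE, n, n, dimnames = list(Lp, Lp))
  for (comp in comps2) {
    if (length(comp) < 2) next
    prs <- utils::combn(comp, 2)
    for (j in seq_len(ncol(prs))) {
      x <- prs[1, j]; y <- prs[2, j]
      if (below_common_child(x, y)) a3[x, y] <- a3[y, x] <- TRUE
    }
  }
  comps3 <- lapply(adj_components(a3), function(i) Lp[i])
  list(comps1 = order_blocks(comps1),
       comps2 = order_blocks(comps2),
       comps3 = order_blocks(comps3),
       h1_keys = pair_key(adj_to_edges(a1)[, 1], adj_to_edges(a1)[, 2]),
       h2_keys = pair_key(adj_to_edges(a2)[, 1], adj_to_edges(a2)[, 2]))
}

#' Construct a relaxed (or restricted) scenario explaining a 3-partition
#'
#' Implements the recursive gene-tree construction: a species tree agreeing
#' with the partition's species triples is fixed (or supplied), dated with
#' the default leaf-0 / scale-3 time map, and the gene tree is built top-down
#' with reconciliation and stamps assigned on the fly.  With
#' `restricted = TRUE` the free choice of the child edge for H2 components is
#' constrained so that the output additionally satisfies the witness axioms
#' S4-S6.  The returned scenario's divergence partition equals the input.
#'
#' @param g a `three_partition`.
#' @param restricted construct a restricted scenario?
#' @param species_tree optional `planted_tree` on the colors (it must agree
#'   with the partition's species triple system; extra leaves are allowed).
#' @param tau_S optional time map for the species tree.
#' @param scale time units per height level for the default species dating.
#' @return an `edt_scenario`; attribute `"trace"` records `epsilon` and a
#'   data frame of all vertices created during the recursion (`role` is one
#'   of `"rho_prime"`, `"u_i"`, `"v_j"`, `"leaf"`; `u_S` the species vertex
#'   of the recursion step; `tau` the stamp; `members` the gene subset).
#' @export
build_scenario <- function(g, restricted = FALSE, species_tree = NULL,
                           tau_S = NULL, scale = 3) {
  stopifnot(inherits(g, "three_partition"))
  if (length(g$vertices) == 0) stop("empty gene set")
  verdict <- is_valid_input(g)
  if (!verdict$explainable) {
    stop("not explainable by a relaxed scenario; failed condition: ",
         verdict$failed_condition)
  }
  if (is.null(species_tree)) {
    S <- verdict$species_tree
  } else {
    S <- species_tree
    if (!all(unique(unname(g$sigma)) %in% tree_leaves(S))) {
      stop("supplied species tree misses colors of the partition")
    }
    if (!agrees(S, species_triples(g))) {
      stop("supplied species tree does not agree with the partition's species triples")
    }
  }
  if (is.null(tau_S)) tau_S <- assign_time_map(S, 0, scale)
  check_time_map(S, tau_S)
  eps <- epsilon_margin(S, tau_S)

  env <- new.env(parent = emptyenv())
  env$labels <- character(0); env$parent <- integer(0)
  env$children <- list(); env$tau <- numeric(0); env$mu <- list()
  env$counter <- 0L
  env$trace <- list()
  gene_set <- g$vertices
  new_vertex <- function(label, parent_idx, tau, mu, role, uS, members) {
    i <- length(env$labels) + 1L
    env$labels[i] <- label
    env$parent[i] <- parent_idx
    env$children[[i]] <- integer(0)
    if (!is.na(parent_idx)) {
      env$children[[parent_idx]] <- c(env$children[[parent_idx]], i)
    }
    env$tau[i] <- tau
    env$mu[[i]] <- mu
    env$trace[[length(env$trace) + 1L]] <-
      list(role = role, label = label, u_S = uS, tau = tau,
           members = paste(members, collapse = ","))
    i
  }
  fresh <- function() {
    env$counter <- env$counter + 1L
    lab <- paste0("t", env$counter)
    while (lab %in% gene_set) lab <- paste0(lab, "_")
    lab
  }
  S_sub <- .subtree_leaves(S)
  child_for_colors <- function(uS_idx, cols, need_all) {
    # children of uS whose subtree meets (need_all: contains) cols; pick the
    # candidate holding the smallest color
    cand <- integer(0)
    for (c in S$children[[uS_idx]]) {
      lv <- S_sub[[c]]
      if (need_all) {
        if (all(cols %in% lv)) cand <- c(cand, c)
      } else if (any(cols %in% lv)) cand <- c(cand, c)
    }
    if (length(cand) == 0) stop("internal error: no feasible child of u_S")
    cols <- sort(cols, method = "radix")
    for (col in cols) {
      for (c in cand) if (col %in% S_sub[[c]]) return(c)
    }
    cand[1]
  }

  build <- function(Lp, uS_idx) {
    uS <- S$labels[uS_idx]
    p_idx <- S$parent[uS_idx]
    rho <- new_vertex(fresh(), NA_integer_, tau_S[[uS]] + eps,
                      c(S$labels[p_idx], uS), "rho_prime", uS, Lp)
    if (S$is_leaf[uS_idx]) {
      for (x in sort(Lp, method = "radix")) {
        new_vertex(x, rho, tau_S[[uS]], g$sigma[[x]], "leaf", uS, x)
      }
      return(rho)
    }
    aux <- auxiliary_graphs(g, Lp, uS, S)
    # invariant: no PDT edge inside an H1 component whose colors meet at uS
    for (Ci in aux$comps1) {
      if (length(Ci) < 2) next
      prs <- utils::combn(Ci, 2)
      for (j in seq_len(ncol(prs))) {
        x <- prs[1, j]; y <- prs[2, j]
        if (g$rel[[pair_key(x, y)]] == "GT" &&
            tree_lca(S, c(g$sigma[[x]], g$sigma[[y]])) == uS) {
          stop("internal error: PDT edge inside an H1 component meeting at u_S")
        }
      }
    }
    comp_of2 <- function(x) {
      for (i in seq_along(aux$comps2)) if (x %in% aux$comps2[[i]]) return(i)
      stop("internal error: vertex outside every H2 component")
    }
    for (Ci in aux$comps1) {
      ui <- new_vertex(fresh(), rho, tau_S[[uS]], uS, "u_i", uS, Ci)
      in_Ci <- vapply(aux$comps2, function(b) all(b %in% Ci), logical(1))
      comps2_in <- which(in_Ci)
      forced <- list()
      if (restricted && length(comps2_in) >= 2) {
        # pick the lexicographically smallest H1-minus-H2 edge inside Ci and
        # anchor the two H2 components it straddles to distinct children
        prs <- utils::combn(sort(Ci, method = "radix"), 2)
        pick <- NULL
        for (j in seq_len(ncol(prs))) {
          k <- pair_key(prs[1, j], prs[2, j])
          if (k %in% aux$h1_keys && !(k %in% aux$h2_keys)) {
            pick <- prs[, j]
            break
          }
        }
        if (is.null(pick)) stop("internal error: no H1\\H2 edge in a split H1 component")
        for (endpoint in pick) {
          forced[[as.character(comp_of2(endpoint))]] <-
            child_for_colors(uS_idx, g$sigma[[endpoint]], need_all = FALSE)
        }
      }
      for (ci2 in comps2_in) {
        Cj <- aux$comps2[[ci2]]
        key <- as.character(ci2)
        vstar <- if (!is.null(forced[[key]])) {
          forced[[key]]
        } else {
          child_for_colors(uS_idx, unique(unname(g$sigma[Cj])), need_all = FALSE)
        }
        vj <- new_vertex(fresh(), ui, tau_S[[uS]] - eps,
                         c(uS, S$labels[vstar]), "v_j", uS, Cj)
        in_Cj <- vapply(aux$comps3, function(b) all(b %in% Cj), logical(1))
        for (Ck in aux$comps3[in_Cj]) {
          vS <- child_for_colors(uS_idx, unique(unname(g$sigma[Ck])), need_all = TRUE)
          sub <- build(Ck, vS)
          env$parent[sub] <- vj
          env$children[[vj]] <- c(env$children[[vj]], sub)
        }
      }
    }
    rho
  }

  top <- build(gene_set, S$root)
  # leaf-set bookkeeping check (every created vertex spans exactly the gene
  # subset of its recursion step)
  .assert_spans(env, gene_set)
  planted_lab <- "0"
  while (planted_lab %in% env$labels) planted_lab <- paste0(planted_lab, "_")
  pr <- length(env$labels) + 1L
  env$labels[pr] <- planted_lab
  env$parent[pr] <- NA_integer_
  env$children[[pr]] <- top
  env$parent[top] <- pr
  env$tau[pr] <- tau_S[[S$labels[S$planted_root]]]
  env$mu[[pr]] <- S$labels[S$planted_root]

  keep <- .suppress_unary(env, pr)
  labs <- env$labels[keep]
  par_lab <- ifelse(is.na(env$parent[keep]), NA_character_, env$labels[env$parent[keep]])
  p <- stats::setNames(par_lab, labs)
  ord <- stats::setNames(lapply(keep, function(i) env$labels[env$children[[i]]]), labs)
  ord <- ord[lengths(ord) > 0]
  T <- planted_tree(p, children_order = ord)
  tau_T <- stats::setNames(env$tau[keep], labs)
  mu <- stats::setNames(env$mu[keep], labs)
  out <- scenario(T, S, g$sigma, mu, tau_T, tau_S)
  viol <- validate_relaxed(out)
  if (nrow(viol) > 0) stop("internal error: constructed scenario violates ",
                           paste(unique(viol$axiom), collapse = ", "))
  tr <- do.call(rbind, lapply(env$trace, function(x) {
    data.frame(role = x$role, label = x$label, u_S = x$u_S, tau = x$tau,
               members = x$members)
  }))
  attr(out, "trace") <- list(epsilon = eps, vertices = tr)
  out
}

# verify L(T'(v)) equals the recorded member set for every created vertex
.assert_spans <- function(env, gene_set) {
  n <- length(env$labels)
  span <- vector("list", n)
  # postorder over the forest rooted at vertices with NA parent
  order <- integer(0)
  roots <- which(is.na(env$parent[seq_len(n)]))
  s1 <- roots; s2 <- integer(0)
  while (length(s1) > 0) {
    v <- s1[length(s1)]; s1 <- s1[-length(s1)]
    s2 <- c(s2, v)
    s1 <- c(s1, env$children[[v]])
  }
  for (v in rev(s2)) {
    if (length(env$children[[v]]) == 0) {
      span[[v]] <- if (env$labels[v] %in% gene_set) env$labels[v] else character(0)
    } else {
      span[[v]] <- unlist(lapply(env$children[[v]], function(c) span[[c]]))
    }
  }
  for (i in seq_along(env$trace)) {
    rec <- env$trace[[i]]
    v <- match(rec$label, env$labels)
    want <- sort(strsplit(rec$members, ",", fixed = TRUE)[[1]], method = "radix")
    have <- sort(span[[v]], method = "radix")
    if (!identical(want, have)) {
      stop("internal error: vertex ", rec$label, " spans {",
           paste(have, collapse = ","), "} instead of {",
           paste(want, collapse = ","), "}")
    }
  }
  invisible(TRUE)
}

# drop unary inner vertices (all except the planted root pr and leaves);
# returns the sorted indices that survive
.suppress_unary <- function(env, pr) {
  n <- length(env$labels)
  drop <- logical(n)
  for (v in seq_len(n)) {
    if (v == pr) next
    if (length(env$children[[v]]) == 1L) drop[v] <- TRUE
  }
  for (v in which(drop)) {
    # splice the (current, unique) child to the (current) parent; processing
    # every dropped vertex once resolves arbitrary chains because both
    # pointers are read at processing time
    child <- env$children[[v]][1]
    parent <- env$parent[v]
    env$parent[child] <- parent
    pos <- match(v, env$children[[parent]])
    env$children[[parent]][pos] <- child
    env$children[[v]] <- integer(0)
  }
  which(!drop)
}
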