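# Relaxed and restricted evolutionary scenarios.
#
# A scenario bundles a dated gene tree (T, tauT), a dated species tree
# (S, tauS), a leaf coloring sigma: L(T) -> L(S) and a reconciliation map mu
# sending every gene-tree vertex to a vertex or an edge of S.  Time
# consistency (axioms S0-S3) makes the bundle a *relaxed* scenario; the
# witness axioms S4-S6 single out *restricted* scenarios.

#' Numeric tolerance for time-stamp comparison
#'
#' Stamps are compared with an absolute tolerance, configurable through
#' `options(edtgraph.tol = ...)`.  The simulator emits stamps that stay well
#' clear of the tolerance, so comparisons behave as if exact.
#'
#' @return a positive numeric scalar (default `1e-9`).
#' @export
edt_tol <- function() getOption("edtgraph.tol", 1e-9)

time_eq <- function(a, b, tol = edt_tol()) abs(a - b) <= tol
time_cmp <- function(a, b, tol = edt_tol()) {
  if (abs(a - b) <= tol) 0L else if (a < b) -1L else 1L
}

# --- reconciliation locations ------------------------------------------------
# A location is a character vector: length 1 = vertex, length 2 = (parent,
# child) edge of S.

loc_is_edge <- function(loc) length(loc) == 2L

check_location <- function(S, loc, what = "mu") {
  loc <- as.character(loc)
  if (!length(loc) %in% 1:2) stop(what, ": location must have length 1 or 2")
  ii <- v_index(S, loc)
  if (length(loc) == 2L) {
    if (is.na(S$parent[ii[2]]) || S$parent[ii[2]] != ii[1]) {
      stop(what, ": (", loc[1], ",", loc[2], ") is not an edge of the species tree")
    }
  }
  loc
}

# partial order on V(S) u E(S):  loc1 <= loc2 ?
#  - vertex x <= vertex y   iff x below y
#  - vertex x <= edge (u,v) iff x below v
#  - edge (u,v) <= vertex x iff u below x
#  - edge (u,v) <= edge (a,b) iff v below b
loc_leq <- function(S, l1, l2) {
  if (!loc_is_edge(l1) && !loc_is_edge(l2)) {
    .below(S, v_index(S, l1), v_index(S, l2))
  } else if (!loc_is_edge(l1)) {
    .below(S, v_index(S, l1), v_index(S, l2[2]))
  } else if (!loc_is_edge(l2)) {
    .below(S, v_index(S, l1[1]), v_index(S, l2))
  } else {
    .below(S, v_index(S, l1[2]), v_index(S, l2[2]))
  }
}

loc_comparable <- function(S, l1, l2) loc_leq(S, l1, l2) || loc_leq(S, l2, l1)

loc_eq <- function(l1, l2) length(l1) == length(l2) && all(l1 == l2)

#' Construct a relaxed-scenario bundle
#'
#' Performs structural validation only (labels resolve, maps are total);
#' axiom checking is done by [validate_relaxed()] so that invalid bundles can
#' be constructed and diagnosed.
#'
#' @param gene_tree,species_tree `planted_tree`s.
#' @param sigma named character vector: gene leaf -> species leaf.
#' @param mu named list: gene vertex -> species vertex label, or a length-2
#'   character vector `(parent, child)` denoting an edge of the species tree.
#' @param tau_T,tau_S named numeric time maps over all vertices of the
#'   respective tree.
#' @return an object of class `edt_scenario`.
#' @export
scenario <- function(gene_tree, species_tree, sigma, mu, tau_T, tau_S) {
  stopifnot(inherits(gene_tree, "planted_tree"),
            inherits(species_tree, "planted_tree"))
  gl <- tree_leaves(gene_tree)
  if (!all(gl %in% names(sigma))) stop("sigma must color every gene leaf")
  sigma <- stats::setNames(as.character(sigma[gl]), gl)
  if (!all(sigma %in% tree_leaves(species_tree))) {
    stop("sigma must map into the species leaves")
  }
  gv <- tree_vertices(gene_tree)
  if (!all(gv %in% names(mu))) {
    stop("mu must be total on the gene-tree vertices; missing: ",
         paste(setdiff(gv, names(mu)), collapse = ", "))
  }
  mu <- lapply(stats::setNames(gv, gv),
               function(v) check_location(species_tree, mu[[v]]))
  if (!all(gv %in% names(tau_T))) stop("tau_T must cover the gene tree")
  if (!all(tree_vertices(species_tree) %in% names(tau_S))) {
    stop("tau_S must cover the species tree")
  }
  check_time_map(gene_tree, tau_T)
  check_time_map(species_tree, tau_S)
  structure(list(gene_tree = gene_tree, species_tree = species_tree,
                 sigma = sigma, mu = mu,
                 tau_T = tau_T[gv],
                 tau_S = tau_S[tree_vertices(species_tree)]),
            class = "edt_scenario")
}

#' @export
print.edt_scenario <- function(x, ...) {
  cat("scenario:", length(tree_leaves(x$gene_tree)), "genes over",
      length(tree_leaves(x$species_tree)), "species;",
      sum(hgt_edges(x)$lam == 1L), "HGT edge(s)\n")
  cat("  T:", write_newick(x$gene_tree), "\n  S:", write_newick(x$species_tree), "\n")
  invisible(x)
}

#' Check the relaxed-scenario axioms
#'
#' Verifies time consistency (S0)-(S3) exhaustively and reports every
#' violation rather than failing fast:
#' * S0: mu(x) is the planted species root iff x is the planted gene root;
#' * S1: mu(x) is a species leaf iff x is a gene leaf, and then mu(x) =
#'   sigma(x);
#' * S2: if mu(x) is a vertex, its species stamp equals the gene stamp;
#' * S3: if mu(x) is an edge (u,v), the gene stamp lies strictly between the
#'   stamps of v and u.
#'
#' @param s an `edt_scenario`.
#' @param tol time tolerance, see [edt_tol()].
#' @return a data frame with columns `axiom`, `vertex`, `detail`; zero rows
#'   mean the bundle is a valid relaxed scenario.
#' @export
validate_relaxed <- function(s, tol = edt_tol()) {
  T <- s$gene_tree; S <- s$species_tree
  out <- list()
  bad <- function(axiom, vertex, detail) {
    out[[length(out) + 1L]] <<- data.frame(axiom = axiom, vertex = vertex,
                                           detail = detail)
  }
  s_planted <- S$labels[S$planted_root]
  t_planted <- T$labels[T$planted_root]
  for (v in tree_vertices(T)) {
    m <- s$mu[[v]]
    maps_to_0S <- !loc_is_edge(m) && m == s_planted
    if (maps_to_0S != (v == t_planted)) {
      bad("S0", v, "planted roots must correspond under mu")
    }
    is_gene_leaf <- T$is_leaf[v_index(T, v)]
    maps_to_leaf <- !loc_is_edge(m) && S$is_leaf[v_index(S, m)]
    if (maps_to_leaf != is_gene_leaf) {
      bad("S1", v, "mu maps leaves to leaves and only leaves to leaves")
    } else if (is_gene_leaf && m != s$sigma[[v]]) {
      bad("S1", v, paste0("mu(", v, ") = ", m, " differs from sigma = ", s$sigma[[v]]))
    }
    if (!loc_is_edge(m)) {
      if (!time_eq(s$tau_S[[m]], s$tau_T[[v]], tol)) {
        bad("S2", v, sprintf("tau_T = %g but tau_S(%s) = %g",
                             s$tau_T[[v]], m, s$tau_S[[m]]))
      }
    } else {
      lo <- s$tau_S[[m[2]]]; hi <- s$tau_S[[m[1]]]
      t <- s$tau_T[[v]]
      if (!(time_cmp(lo, t, tol) < 0 && time_cmp(t, hi, tol) < 0)) {
        bad("S3", v, sprintf("tau_T = %g not strictly inside (%g, %g)", t, lo, hi))
      }
    }
  }
  if (length(out) == 0) {
    data.frame(axiom = character(0), vertex = character(0), detail = character(0))
  } else {
    do.call(rbind, out)
  }
}

#' Is the bundle a valid relaxed scenario?
#' @param s an `edt_scenario`.
#' @param tol time tolerance.
#' @return logical scalar.
#' @export
is_valid_scenario <- function(s, tol = edt_tol()) nrow(validate_relaxed(s, tol)) == 0

#' HGT labeling of the gene-tree edges
#'
#' An edge (u,v) of the gene tree is a horizontal-transfer edge precisely
#' when mu(u) and mu(v) are incomparable in the species tree (with the
#' ancestor order extended to vertices and edges).
#'
#' @param s an `edt_scenario`.
#' @return a list with components `edges` (two-column matrix, parent/child)
#'   and `lam` (integer 0/1 labels).
#' @export
hgt_edges <- function(s) {
  T <- s$gene_tree; S <- s$species_tree
  eu <- character(0); ev <- character(0); lam <- integer(0)
  for (v in seq_along(T$labels)) {
    p <- T$parent[v]
    if (is.na(p)) next
    l1 <- s$mu[[T$labels[p]]]; l2 <- s$mu[[T$labels[v]]]
    eu <- c(eu, T$labels[p]); ev <- c(ev, T$labels[v])
    lam <- c(lam, as.integer(!loc_comparable(S, l1, l2)))
  }
  list(edges = cbind(parent = eu, child = ev), lam = lam)
}

#' Is a scenario free of horizontal transfer?
#' @param s an `edt_scenario`.
#' @return logical scalar.
#' @export
is_hgt_free <- function(s) all(hgt_edges(s)$lam == 0L)

#' Witness leaves of every gene-tree vertex
#'
#' A leaf x witnesses a vertex v when x lies below v and the path from v down
#' to x contains no HGT edge.  Every leaf witnesses itself.  A scenario is
#' *fully witnessed* when every vertex has at least one witness.
#'
#' @param s an `edt_scenario`.
#' @return a named list mapping each gene-tree vertex to its witness leaves.
#' @export
witnesses <- function(s) {
  T <- s$gene_tree
  h <- hgt_edges(s)
  hgt_child <- stats::setNames(h$lam, h$edges[, "child"])
  out <- vector("list", length(T$labels))
  for (v in .postorder(T)) {
    if (T$is_leaf[v]) {
      out[[v]] <- T$labels[v]
    } else {
      w <- character(0)
      for (c in T$children[[v]]) {
        if (hgt_child[[T$labels[c]]] == 0L) w <- c(w, out[[c]])
      }
      out[[v]] <- w
    }
  }
  stats::setNames(out, T$labels)
}

#' @rdname witnesses
#' @export
is_fully_witnessed <- function(s) all(lengths(witnesses(s)) > 0)

#' Check the restricted-scenario axioms S4-S6
#'
#' On top of a valid relaxed scenario, a *restricted* scenario is
#' fully witnessed (S4), maps children of speciation-like vertices strictly
#' below (S5), and has every speciation-like vertex witnessed by a leaf pair
#' whose gene and species last common ancestors line up (S6).
#'
#' @param s an `edt_scenario` that passes [validate_relaxed()].
#' @return a data frame of violations (`axiom`, `vertex`, `detail`); zero
#'   rows mean the scenario is restricted.
#' @export
validate_restricted <- function(s) {
  T <- s$gene_tree; S <- s$species_tree
  out <- list()
  bad <- function(axiom, vertex, detail) {
    out[[length(out) + 1L]] <<- data.frame(axiom = axiom, vertex = vertex,
                                           detail = detail)
  }
  wit <- witnesses(s)
  unw <- names(wit)[lengths(wit) == 0]
  for (v in unw) bad("S4", v, "vertex has no witness")
  inner_S <- tree_inner(S)
  for (v in seq_along(T$labels)) {
    lab <- T$labels[v]
    m <- s$mu[[lab]]
    if (loc_is_edge(m) || !(m %in% inner_S)) next
    # S5
    for (c in T$children[[v]]) {
      mc <- s$mu[[T$labels[c]]]
      if (!(loc_leq(S, mc, m) && !loc_eq(mc, m))) {
        bad("S5", lab, paste0("child ", T$labels[c],
                              " not mapped strictly below mu(", lab, ") = ", m))
      }
    }
    # S6: some witness pair x,y with lca_T = v and lca_S(sigma x, sigma y) = mu(v)
    wv <- wit[[lab]]
    ok <- FALSE
    if (length(wv) >= 2) {
      for (i in seq_along(wv)) {
        for (j in seq_along(wv)) {
          if (j <= i) next
          x <- wv[i]; y <- wv[j]
          if (tree_lca(T, c(x, y)) == lab &&
              tree_lca(S, c(s$sigma[[x]], s$sigma[[y]])) == m) {
            ok <- TRUE
            break
          }
        }
        if (ok) break
      }
    }
    if (!ok) bad("S6", lab,
                 paste0("no witness pair with matching last common ancestors at ", m))
  }
  if (length(out) == 0) {
    data.frame(axiom = character(0), vertex = character(0), detail = character(0))
  } else {
    do.call(rbind, out)
  }
}

#' Genericity of a scenario
#'
#' A scenario is generic when equal time stamps force the reconciliation: if
#' an inner gene vertex v and an inner species vertex U satisfy
#' tau_T(v) = tau_S(U) then mu(v) = U.  The simulator produces generic
#' scenarios by construction (jittered event times).
#'
#' @param s an `edt_scenario`.
#' @param tol time tolerance.
#' @return logical scalar.
#' @export
is_generic <- function(s, tol = edt_tol()) {
  T <- s$gene_tree; S <- s$species_tree
  for (v in tree_inner(T)) {
    for (U in tree_inner(S)) {
      if (time_eq(s$tau_T[[v]], s$tau_S[[U]], tol)) {
        m <- s$mu[[v]]
        if (loc_is_edge(m) || m != U) return(FALSE)
      }
    }
  }
  TRUE
}
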