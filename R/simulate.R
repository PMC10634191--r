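# Synthetic scenario generator and canonical worked-example fixtures.
#
# The generator grows a gene tree forward in time inside a dated species
# tree.  A lineage traversing a species edge may duplicate (both copies stay
# on the edge) or emit a transfer to a contemporaneous incomparable species
# edge; on reaching a speciation vertex it is reconciled with that vertex and
# continues into every child edge (optionally with extra copies into a single
# child edge -- relaxed scenarios explicitly allow several descendants of a
# "speciation" vertex in one lineage, and this is what makes non-cograph EDT
# structure reachable).  Event stamps are jittered away from all species
# stamps, so generated scenarios are generic by construction unless jitter is
# disabled.

#' Simulate a random relaxed scenario
#'
#' @param n_species number of species (>= 1).
#' @param n_genes number of extant genes (>= 1); growth is retried with a
#'   boosted duplication rate and finally padded with terminal duplications
#'   or pruned uniformly at random to hit the target exactly.
#' @param transfer_prob per-edge-traversal probability of a horizontal
#'   transfer attempt (skipped when no contemporaneous incomparable species
#'   edge exists).
#' @param dup_prob per-edge-traversal probability of a duplication.
#' @param binary_only force binary species and gene trees.
#' @param hgt_free force `transfer_prob = 0`.
#' @param seed integer seed; the global RNG state is restored on exit, and
#'   equal seeds yield identical scenarios.
#' @param jitter jitter event stamps away from all species stamps (generic
#'   scenarios); with `jitter = FALSE` event stamps are placed on species
#'   stamps whenever possible, producing non-generic cases.
#' @param lump_prob probability that a speciation passes an extra gene copy
#'   into one of its child edges (0 when `binary_only`).
#' @return a valid `edt_scenario`.
#' @export
random_scenario <- function(n_species, n_genes, transfer_prob = 0.2,
                            dup_prob = 0.2, binary_only = FALSE,
                            hgt_free = FALSE, seed = 1, jitter = TRUE,
                            lump_prob = if (binary_only) 0 else 0.15) {
  stopifnot(n_species >= 1, n_genes >= 1,
            transfer_prob >= 0, transfer_prob <= 1,
            dup_prob >= 0, dup_prob <= 1,
            lump_prob >= 0, lump_prob <= 1)
  if (hgt_free) transfer_prob <- 0
  if (binary_only) lump_prob <- 0
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed %% .Machine$integer.max))

  S <- .random_species_tree(n_species, binary_only)
  tau_S <- assign_time_map(S, 0, 3)
  if (jitter) {
    # distinct stamps for inner species vertices: two concurrent speciation
    # vertices would make every scenario through them non-generic
    inner <- tree_inner(S)
    if (length(inner) > 0) {
      offs <- sample(0.9 * seq_along(inner) / (length(inner) + 1))
      tau_S[inner] <- tau_S[inner] + offs
    }
    check_time_map(S, tau_S)
  }

  dp <- dup_prob
  sc <- NULL
  for (try in 1:6) {
    sc <- .grow_gene_tree(S, tau_S, transfer_prob, dp, lump_prob, jitter,
                          cap = max(4L * n_genes, 40L))
    if (length(sc$leaves) >= n_genes) break
    dp <- min(0.45, dp + 0.08)
  }
  while (length(sc$leaves) < n_genes) {
    sc <- .split_random_leaf(sc, S, tau_S, jitter)
  }
  if (length(sc$leaves) > n_genes) {
    keep <- sort(sample(sc$leaves, n_genes))
    sc <- .prune_to(sc, keep)
  }
  out <- .finish_scenario(sc, S, tau_S)
  viol <- validate_relaxed(out)
  if (nrow(viol) > 0) stop("internal error: generator produced an invalid scenario")
  out
}

.species_labels <- function(n) {
  if (n <= 26) LETTERS[seq_len(n)] else sprintf("S%03d", seq_len(n))
}

.random_species_tree <- function(n, binary_only) {
  labs <- .species_labels(n)
  if (n == 1) {
    p <- c(NA_character_, "0")
    names(p) <- c("0", labs)
    return(planted_tree(p))
  }
  active <- as.list(labs)
  while (length(active) > 1) {
    k <- if (binary_only || length(active) < 3 || stats::runif(1) > 0.3) 2 else 3
    pick <- sample(length(active), k)
    merged <- list(children = active[pick])
    active <- c(active[-pick], list(merged))
  }
  tree_from_nested(active[[1]])
}

# growth state: environment with labels/parent/children/tau/mu/leaves
.grow_gene_tree <- function(S, tau_S, transfer_prob, dup_prob, lump_prob,
                            jitter, cap) {
  env <- new.env(parent = emptyenv())
  env$labels <- character(0); env$parent <- integer(0)
  env$children <- list(); env$tau <- numeric(0); env$mu <- list()
  env$leaves <- character(0)
  env$nleaf <- 0L; env$count <- 0L
  stamps <- sort(unique(unname(tau_S)))
  add <- function(label, parent, tau, mu) {
    i <- length(env$labels) + 1L
    env$labels[i] <- label; env$parent[i] <- parent
    env$children[[i]] <- integer(0)
    if (!is.na(parent)) env$children[[parent]] <- c(env$children[[parent]], i)
    env$tau[i] <- tau; env$mu[[i]] <- mu
    env$count <- env$count + 1L
    i
  }
  inner_lab <- function() paste0("i", length(env$labels) + 1L)
  pick_time <- function(lo, hi) {
    if (!jitter) {
      inside <- stamps[stamps > lo + 1e-3 & stamps < hi - 1e-3]
      if (length(inside) > 0) return(inside[1])
      return((lo + hi) / 2)
    }
    for (a in 1:50) {
      t <- stats::runif(1, lo, hi)
      if (min(abs(t - stamps)) > 1e-3 && t - lo > 1e-3 && hi - t > 1e-3) return(t)
    }
    NA_real_
  }
  S_edges <- which(!is.na(S$parent))
  transfer_target <- function(u, v, t) {
    # species edges (p,q), incomparable with (u,v), alive at time t
    ok <- integer(0)
    for (q in S_edges) {
      p <- S$parent[q]
      if (!(tau_S[[S$labels[q]]] < t && t < tau_S[[S$labels[p]]])) next
      if (.below(S, v, q) || .below(S, q, v)) next
      ok <- c(ok, q)
    }
    if (length(ok) == 0) return(NULL)
    ok[sample.int(length(ok), 1)]
  }
  grow <- function(u, v, t_in, parent_idx) {
    # lineage on species edge (u, v), entering at time t_in; creates and
    # returns the next gene vertex
    lo <- tau_S[[S$labels[v]]]
    edge_mu <- c(S$labels[u], S$labels[v])
    if (env$count < cap) {
      if (stats::runif(1) < transfer_prob) {
        t <- pick_time(lo, t_in)
        q <- if (is.na(t)) NULL else transfer_target(u, v, t)
        if (!is.null(q)) {
          w <- add(inner_lab(), parent_idx, t, edge_mu)
          grow(u, v, t, w)
          grow(S$parent[q], q, t, w)
          return(w)
        }
      }
      if (stats::runif(1) < dup_prob) {
        t <- pick_time(lo, t_in)
        if (!is.na(t)) {
          w <- add(inner_lab(), parent_idx, t, edge_mu)
          grow(u, v, t, w)
          grow(u, v, t, w)
          return(w)
        }
      }
    }
    if (S$is_leaf[v]) {
      env$nleaf <- env$nleaf + 1L
      lab <- paste0("g", env$nleaf)
      i <- add(lab, parent_idx, tau_S[[S$labels[v]]], S$labels[v])
      env$leaves <- c(env$leaves, lab)
      return(i)
    }
    w <- add(inner_lab(), parent_idx, tau_S[[S$labels[v]]], S$labels[v])
    for (c in S$children[[v]]) {
      copies <- 1L
      if (env$count < cap && stats::runif(1) < lump_prob) copies <- 2L
      for (r in seq_len(copies)) grow(v, c, tau_S[[S$labels[v]]], w)
    }
    w
  }
  pr <- S$planted_root
  root_idx <- grow(pr, S$root, tau_S[[S$labels[pr]]], NA_integer_)
  env$root <- root_idx
  env
}

.split_random_leaf <- function(env, S, tau_S, jitter) {
  lab <- sample(env$leaves, 1)
  i <- match(lab, env$labels)
  sp <- env$mu[[i]]          # species leaf label
  spi <- v_index(S, sp)
  ps <- S$parent[spi]
  cap_t <- min(env$tau[env$parent[i]], tau_S[[S$labels[ps]]])
  stamps <- sort(unique(unname(tau_S)))
  t <- NA_real_
  for (a in 1:50) {
    cand <- stats::runif(1, tau_S[[sp]], cap_t)
    if (min(abs(cand - stamps)) > 1e-3 && cand - tau_S[[sp]] > 1e-3 &&
        cap_t - cand > 1e-3) { t <- cand; break }
  }
  if (is.na(t)) t <- (tau_S[[sp]] + cap_t) / 2
  d <- length(env$labels) + 1L
  env$labels[d] <- paste0("i", d)
  env$parent[d] <- env$parent[i]
  env$children[[d]] <- integer(0)
  env$tau[d] <- t
  env$mu[[d]] <- c(S$labels[ps], sp)
  pos <- match(i, env$children[[env$parent[i]]])
  env$children[[env$parent[i]]][pos] <- d
  env$parent[i] <- d
  env$children[[d]] <- i
  env$nleaf <- env$nleaf + 1L
  lab2 <- paste0("g", env$nleaf)
  j <- length(env$labels) + 1L
  env$labels[j] <- lab2
  env$parent[j] <- d
  env$children[[j]] <- integer(0)
  env$tau[j] <- tau_S[[sp]]
  env$mu[[j]] <- sp
  env$children[[d]] <- c(env$children[[d]], j)
  env$leaves <- c(env$leaves, lab2)
  env
}

.prune_to <- function(env, keep) {
  n <- length(env$labels)
  is_leaf <- lengths(env$children) == 0
  alive <- logical(n)
  for (lab in keep) {
    v <- match(lab, env$labels)
    while (!is.na(v) && !alive[v]) {
      alive[v] <- TRUE
      v <- env$parent[v]
    }
  }
  for (v in seq_len(n)) {
    if (!alive[v]) {
      p <- env$parent[v]
      if (!is.na(p) && alive[p]) {
        env$children[[p]] <- setdiff(env$children[[p]], v)
      }
    }
  }
  # suppress unary inner vertices among the alive ones
  changed <- TRUE
  while (changed) {
    changed <- FALSE
    for (v in which(alive)) {
      if (v == env$root) next
      if (!is_leaf[v] && length(env$children[[v]]) == 1L) {
        c <- env$children[[v]][1]
        p <- env$parent[v]
        alive[v] <- FALSE
        env$parent[c] <- p
        if (!is.na(p)) {
          pos <- match(v, env$children[[p]])
          env$children[[p]][pos] <- c
        }
        env$children[[v]] <- integer(0)
        changed <- TRUE
      }
    }
  }
  # the root itself may have become unary (or dead weight)
  while (length(env$children[[env$root]]) == 1L) {
    old <- env$root
    env$root <- env$children[[old]][1]
    alive[old] <- FALSE
    env$parent[env$root] <- NA_integer_
  }
  env$alive <- alive
  env$leaves <- intersect(env$leaves, env$labels[alive])
  env
}

.finish_scenario <- function(env, S, tau_S) {
  n <- length(env$labels)
  alive <- if (is.null(env$alive)) rep(TRUE, n) else env$alive
  keep <- which(alive)
  labs <- env$labels[keep]
  planted <- "0"
  while (planted %in% labs) planted <- paste0(planted, "_")
  par_lab <- vapply(keep, function(i) {
    if (i == env$root || is.na(env$parent[i])) planted else env$labels[env$parent[i]]
  }, character(1))
  p <- c(stats::setNames(NA_character_, planted), stats::setNames(par_lab, labs))
  ord <- stats::setNames(lapply(keep, function(i) env$labels[env$children[[i]]]), labs)
  ord <- ord[lengths(ord) > 0]
  T <- planted_tree(p, children_order = ord)
  tau_T <- c(stats::setNames(tau_S[[S$labels[S$planted_root]]], planted),
             stats::setNames(env$tau[keep], labs))
  mu <- c(stats::setNames(list(S$labels[S$planted_root]), planted),
          stats::setNames(env$mu[keep], labs))
  sigma <- stats::setNames(
    vapply(env$leaves, function(l) env$mu[[match(l, env$labels)]], character(1)),
    env$leaves)
  scenario(T, S, sigma, mu, tau_T, tau_S)
}

#' Worked-example fixtures
#'
#' Small instances used throughout the documentation and tests:
#' * `"star_example"`: star gene tree over S = ((X,Y),Z) with the gene root
#'   reconciled with the species root; its EDT graph is `{xz, yz}` and its
#'   PDT graph `{xy}`.
#' * `"c4_example"`: two 2-gene families in two sister species whose EDT
#'   graph is an induced 4-cycle.
#' * `"fig9_partition"`: the 4-gene, 2-color 3-partition used to trace the
#'   builder (LDT `{ab, a'b'}`, EDT `{ab', a'b}`, PDT `{aa', bb'}`).
#' * `"p4_partition"`: an explainable partition whose EDT graph is a P4 on
#'   four colors (exhibits non-cograph EDT and strict quasi-orthology
#'   graphs).
#' * `"c6_partition"`: an explainable partition whose EDT graph is an
#'   induced 6-cycle (hence contains induced paths on 5 vertices).
#' * `"edt_obstruction"`: a synthetic properly colored cograph that is not
#'   an EDT graph (its components force contradictory species triples).
#'
#' @param name one of the fixture names above.
#' @return an `edt_scenario`, `three_partition` or `colored_graph`.
#' @export
fixture <- function(name) {
  switch(
    name,
    star_example = {
      S <- read_newick("((X,Y),Z);")
      T <- read_newick("(x,y,z);")
      tau_S <- assign_time_map(S)
      rho_T <- T$labels[T$root]
      rho_S <- S$labels[S$root]
      mu <- list(x = "X", y = "Y", z = "Z")
      mu[[rho_T]] <- rho_S
      mu[[T$labels[T$planted_root]]] <- S$labels[S$planted_root]
      tau_T <- stats::setNames(c(tau_S[[S$labels[S$planted_root]]],
                                 tau_S[[rho_S]], 0, 0, 0),
                               c(T$labels[T$planted_root], rho_T, "x", "y", "z"))
      scenario(T, S, c(x = "X", y = "Y", z = "Z"), mu, tau_T, tau_S)
    },
    c4_example = {
      S <- read_newick("(A,B);")
      T <- read_newick("((a1,a2),(b1,b2));")
      tau_S <- assign_time_map(S)   # leaves 0, root 3, planted 6
      rho_S <- S$labels[S$root]
      la <- tree_lca(T, c("a1", "a2")); lb <- tree_lca(T, c("b1", "b2"))
      rho_T <- T$labels[T$root]
      mu <- list(a1 = "A", a2 = "A", b1 = "B", b2 = "B")
      mu[[rho_T]] <- rho_S
      mu[[la]] <- c(rho_S, "A")
      mu[[lb]] <- c(rho_S, "B")
      mu[[T$labels[T$planted_root]]] <- S$labels[S$planted_root]
      tau_T <- stats::setNames(c(6, 3, 2, 1, 0, 0, 0, 0),
                               c(T$labels[T$planted_root], rho_T, la, lb,
                                 "a1", "a2", "b1", "b2"))
      scenario(T, S, c(a1 = "A", a2 = "A", b1 = "B", b2 = "B"), mu, tau_T, tau_S)
    },
    fig9_partition = {
      v <- c("a", "a'", "b", "b'")
      sig <- stats::setNames(c("A", "A", "B", "B"), v)
      partition_from_rel(
        v, sig,
        rbind(c("a", "b"), c("a'", "b'"),
              c("a", "b'"), c("a'", "b"),
              c("a", "a'"), c("b", "b'")),
        c("LT", "LT", "EQ", "EQ", "GT", "GT"))
    },
    p4_partition = {
      v <- c("a", "b", "c", "d")
      sig <- stats::setNames(c("A", "B", "C", "D"), v)
      partition_from_rel(
        v, sig,
        rbind(c("a", "b"), c("b", "c"), c("c", "d"),
              c("a", "d"), c("a", "c"), c("b", "d")),
        c("EQ", "EQ", "EQ", "LT", "GT", "GT"))
    },
    c6_partition = {
      v <- c("a", "b", "c", "d", "e", "f")
      sig <- stats::setNames(c("A", "B", "C", "D", "E", "F"), v)
      partition_from_rel(
        v, sig,
        rbind(c("a", "b"), c("b", "c"), c("c", "d"),
              c("d", "e"), c("e", "f"), c("a", "f"),
              c("a", "d"), c("b", "e"), c("c", "f"),
              c("a", "c"), c("c", "e"), c("a", "e"),
              c("b", "d"), c("d", "f"), c("b", "f")),
        c(rep("EQ", 6), rep("LT", 3), rep("GT", 6)))
    },
    edt_obstruction = {
      # a properly colored cograph that no relaxed scenario explains as its
      # EDT graph: the star component forces a required species triple for
      # every placement of its non-edges, while the three path components
      # make exactly those triples forbidden
      v <- c("a", "b", "c", "d",
             "a2", "c2", "b2", "a3", "d3", "b3", "c4", "d4", "a4")
      sig <- stats::setNames(c("A", "B", "C", "D",
                               "A", "C", "B", "A", "D", "B", "C", "D", "A"), v)
      colored_graph(
        v,
        rbind(c("a", "b"), c("b", "c"), c("b", "d"), c("c", "d"),
              c("a2", "c2"), c("c2", "b2"),
              c("a3", "d3"), c("d3", "b3"),
              c("c4", "d4"), c("d4", "a4")),
        sig)
    },
    stop("unknown fixture: ", name)
  )
}
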