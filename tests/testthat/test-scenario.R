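# Relaxed/restricted scenario axioms, HGT labeling, witnesses, genericity.

test_that("the star worked example is a valid, generic, HGT-free scenario", {
  s <- fixture("star_example")
  expect_identical(nrow(validate_relaxed(s)), 0L)
  expect_true(is_valid_scenario(s))
  expect_true(is_generic(s))
  expect_true(is_hgt_free(s))
  expect_true(all(hgt_edges(s)$lam == 0L))
})

test_that("breaking the root stamp is reported as an S2 violation", {
  s <- fixture("star_example")
  rho <- s$gene_tree$labels[s$gene_tree$root]
  tau_bad <- s$tau_T
  tau_bad[[rho]] <- tau_bad[[rho]] - 1  # no longer equals tau_S(rho_S)
  s_bad <- scenario(s$gene_tree, s$species_tree, s$sigma, s$mu, tau_bad, s$tau_S)
  v <- validate_relaxed(s_bad)
  expect_true("S2" %in% v$axiom)
  expect_true(rho %in% v$vertex[v$axiom == "S2"])
})

test_that("structural errors are distinct from axiom violations", {
  s <- fixture("star_example")
  mu_bad <- s$mu
  mu_bad[["x"]] <- "NOPE"
  expect_error(scenario(s$gene_tree, s$species_tree, s$sigma, mu_bad,
                        s$tau_T, s$tau_S), "unknown vertex")
  mu_bad[["x"]] <- c("X", "Y")  # not an edge of S
  expect_error(scenario(s$gene_tree, s$species_tree, s$sigma, mu_bad,
                        s$tau_T, s$tau_S), "not an edge")
})

test_that("HGT labels mark exactly the incomparably reconciled edges", {
  # two sister species; one gene transfers from the A-edge to the B-edge
  S <- read_newick("(A,B);")
  tau_S <- assign_time_map(S)             # A=B=0, root 3, planted 6
  rho_S <- S$labels[S$root]
  T <- read_newick("((a,b),a2);")
  rho_T <- T$labels[T$root]
  w <- tree_lca(T, c("a", "b"))
  mu <- list(a = "A", b = "B", a2 = "A")
  mu[[rho_T]] <- c(rho_S, "A")            # duplication on the A-edge
  mu[[w]] <- c(rho_S, "A")                # transfer vertex, still on A-edge
  mu[[T$labels[T$planted_root]]] <- S$labels[S$planted_root]
  tau_T <- stats::setNames(c(6, 2.5, 1.5, 0, 0, 0),
                           c(T$labels[T$planted_root], rho_T, w, "a", "b", "a2"))
  s <- scenario(T, S, c(a = "A", b = "B", a2 = "A"), mu, tau_T, tau_S)
  expect_identical(nrow(validate_relaxed(s)), 0L)
  h <- hgt_edges(s)
  lam <- stats::setNames(h$lam, h$edges[, "child"])
  expect_identical(unname(lam[["b"]]), 1L)   # edge into B below an A-edge vertex
  expect_identical(unname(lam[["a"]]), 0L)
  expect_identical(unname(lam[[w]]), 0L)
  expect_false(is_hgt_free(s))
})

test_that("HGT labels agree with a brute-force comparability scan", {
  loc_cmp <- function(S, l1, l2) {
    # oracle: enumerate weak descendants of the relevant delimiting vertices
    below_set <- function(l) {
      v <- if (length(l) == 2) l[2] else l
      edtgraph:::.subtree_leaves(S)[[edtgraph:::v_index(S, v)]]
    }
    top_vertex <- function(l) if (length(l) == 2) l[1] else l
    d1 <- below_set(l1); d2 <- below_set(l2)
    all(d1 %in% d2) || all(d2 %in% d1)
  }
  for (i in 1:20) {
    s <- random_scenario(4, 8, transfer_prob = 0.4, seed = 400 + i)
    S <- s$species_tree
    h <- hgt_edges(s)
    for (r in seq_along(h$lam)) {
      l1 <- s$mu[[h$edges[r, "parent"]]]
      l2 <- s$mu[[h$edges[r, "child"]]]
      # comparability of locations coincides with nestedness of the leaf sets
      # below their lower delimiting vertices, except equal-vertex cases that
      # are always comparable
      cmp <- edtgraph:::loc_comparable(S, l1, l2)
      expect_identical(cmp == FALSE, h$lam[r] == 1L)
    }
  }
})

test_that("witnesses: leaves witness themselves, HGT-free scenarios fully", {
  s <- fixture("star_example")
  w <- witnesses(s)
  for (leaf in tree_leaves(s$gene_tree)) expect_true(leaf %in% w[[leaf]])
  # HGT-free: every vertex witnessed by all descendant leaves
  subl <- edtgraph:::.subtree_leaves(s$gene_tree)
  for (i in seq_along(s$gene_tree$labels)) {
    expect_setequal(w[[s$gene_tree$labels[i]]], subl[[i]])
  }
  expect_true(is_fully_witnessed(s))
})

test_that("restricted axioms flag constructed violations", {
  # speciation vertex whose children both map to incomparable edges: the
  # vertex has no witness through either child unless deeper paths are clean;
  # here both children are transferred away, violating S5 (and S6)
  S <- read_newick("((A,B),C);")
  tau_S <- assign_time_map(S)     # inner AB node 3, root 6, planted 9
  rho_S <- S$labels[S$root]
  ab <- tree_lca(S, c("A", "B"))
  T <- read_newick("(x,y);")
  rho_T <- T$labels[T$root]
  mu <- list(x = "A", y = "C")
  mu[[rho_T]] <- ab                      # speciation-like vertex at lca(A,B)
  mu[[T$labels[T$planted_root]]] <- S$labels[S$planted_root]
  tau_T <- stats::setNames(c(9, 3, 0, 0),
                           c(T$labels[T$planted_root], rho_T, "x", "y"))
  s <- scenario(T, S, c(x = "A", y = "C"), mu, tau_T, tau_S)
  expect_identical(nrow(validate_relaxed(s)), 0L)
  v <- validate_restricted(s)
  expect_true("S5" %in% v$axiom)   # child y maps to C-side, not below lca(A,B)
  expect_true("S6" %in% v$axiom)
})

test_that("generator output is valid and self-consistent over many seeds", {
  for (i in 1:60) {
    s <- random_scenario(3 + (i %% 4), 4 + (i %% 8),
                         transfer_prob = 0.3, dup_prob = 0.25, seed = i)
    expect_identical(nrow(validate_relaxed(s)), 0L)
  }
})

test_that("order-theoretic scenario lemmas hold on simulations", {
  # (i) comparable vertices never map to the same inner species vertex;
  # (ii) descendants never map strictly above their ancestors' images;
  # (iii) HGT-free scenarios preserve the order and bound the species lca
  for (i in 1:15) {
    s <- random_scenario(4, 8, transfer_prob = 0.35, seed = 600 + i)
    T <- s$gene_tree; S <- s$species_tree
    labs <- T$labels
    inner_S <- tree_inner(S)
    for (a in seq_along(labs)) {
      anc <- edtgraph:::.anc_path(T, a)
      for (b in anc[-1]) {
        la <- s$mu[[labs[a]]]; lb <- s$mu[[labs[b]]]
        if (!edtgraph:::loc_is_edge(la) && !edtgraph:::loc_is_edge(lb) &&
            la == lb && la %in% inner_S) {
          fail(sprintf("comparable vertices %s, %s share inner image %s",
                       labs[a], labs[b], la))
        }
        # mu(descendant) must not lie strictly above mu(ancestor)
        strictly_above <- edtgraph:::loc_leq(S, lb, la) &&
          !edtgraph:::loc_leq(S, la, lb)
        expect_false(strictly_above)
      }
    }
  }
  for (i in 1:15) {
    s <- random_scenario(4, 8, hgt_free = TRUE, dup_prob = 0.3, seed = 700 + i)
    T <- s$gene_tree; S <- s$species_tree
    labs <- T$labels
    for (a in seq_along(labs)) {
      anc <- edtgraph:::.anc_path(T, a)
      for (b in anc[-1]) {
        expect_true(edtgraph:::loc_leq(S, s$mu[[labs[a]]], s$mu[[labs[b]]]))
      }
    }
    lv <- tree_leaves(T)
    if (length(lv) >= 2) {
      for (pr in utils::combn(lv, 2, simplify = FALSE)) {
        lcaS <- tree_lca(S, c(s$sigma[[pr[1]]], s$sigma[[pr[2]]]))
        lcaT <- tree_lca(T, pr)
        expect_true(edtgraph:::loc_leq(S, lcaS, s$mu[[lcaT]]))
        expect_true(s$tau_S[[lcaS]] <= s$tau_T[[lcaT]] + edt_tol())
      }
    }
  }
})

test_that("fully witnessed + edgeless LDT implies HGT-free", {
  count <- 0L
  for (i in 1:40) {
    s <- random_scenario(4, 7, transfer_prob = if (i %% 2) 0.08 else 0.4,
                         seed = 800 + i)
    if (!is_fully_witnessed(s)) next
    g <- divergence_partition(s)
    if (nrow(g$ldt$edges) > 0) next
    count <- count + 1L
    expect_true(is_hgt_free(s))
  }
  expect_gt(count, 0)
})

test_that("genericity detection", {
  s <- fixture("star_example")
  expect_true(is_generic(s))
  # jittered simulations are generic by construction
  for (i in 1:20) {
    expect_true(is_generic(random_scenario(4, 8, seed = 900 + i)))
  }
  # disabling jitter can produce non-generic scenarios (event stamps placed
  # on species stamps while reconciled with an edge)
  found <- FALSE
  for (i in 1:40) {
    s <- random_scenario(5, 10, transfer_prob = 0.3, dup_prob = 0.35,
                         seed = 950 + i, jitter = FALSE)
    if (!is_generic(s)) { found <- TRUE; break }
  }
  expect_true(found)
})
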