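# Scenario construction from valid 3-partitions.

test_that("auxiliary graphs on the traced 4-gene input", {
  g <- fixture("fig9_partition")
  S <- read_newick("(A,B);")
  aux <- auxiliary_graphs(g, g$vertices, S$labels[S$root], S)
  expect_length(aux$comps1, 1)
  expect_setequal(aux$comps1[[1]], c("a", "a'", "b", "b'"))
  expect_length(aux$comps2, 2)
  expect_identical(aux$comps2[[1]], c("a", "b"))
  expect_identical(aux$comps2[[2]], c("a'", "b'"))
  expect_length(aux$comps3, 4)       # all singletons
  expect_true(all(lengths(aux$comps3) == 1))
})

test_that("edgeless H1 means singleton components", {
  v <- c("p", "q")
  sig <- stats::setNames(c("A", "B"), v)
  g <- partition_from_rel(v, sig, rbind(c("p", "q")), "GT")
  S <- read_newick("(A,B);")
  aux <- auxiliary_graphs(g, v, S$labels[S$root], S)
  expect_length(aux$comps1, 2)
  expect_true(all(lengths(aux$comps1) == 1))
})

test_that("component nesting H3 within H2 within H1 on random valid inputs", {
  nested_in <- function(fine, coarse) {
    all(vapply(fine, function(f) {
      any(vapply(coarse, function(c) all(f %in% c), logical(1)))
    }, logical(1)))
  }
  for (i in 1:12) {
    s <- random_scenario(4, 8, transfer_prob = 0.3, seed = 320 + i)
    g <- divergence_partition(s)
    S <- s$species_tree
    if (S$is_leaf[S$root]) next
    aux <- auxiliary_graphs(g, g$vertices, S$labels[S$root], S)
    expect_true(nested_in(aux$comps2, aux$comps1))
    expect_true(nested_in(aux$comps3, aux$comps2))
  }
})

test_that("epsilon rule: one third of the minimum edge duration", {
  S <- read_newick("(A,B);")
  expect_equal(epsilon_margin(S, assign_time_map(S)), 1)
  tau_unit <- stats::setNames(c(2, 1, 0, 0), c(S$labels[S$planted_root],
                                               S$labels[S$root], "A", "B"))
  expect_equal(epsilon_margin(S, tau_unit), 1 / 3)
  set.seed(21)
  for (rep in 1:10) {
    tr <- rand_tree(sample(3:7, 1))
    lt <- stats::setNames(stats::runif(length(tree_leaves(tr))), tree_leaves(tr))
    tau <- assign_time_map(tr, lt, scale = stats::runif(1, 0.5, 4))
    eps <- epsilon_margin(tr, tau)
    for (v in seq_along(tr$labels)) {
      p <- tr$parent[v]
      if (is.na(p)) next
      expect_lt(2 * eps, tau[[tr$labels[p]]] - tau[[tr$labels[v]]] + 1e-12)
    }
  }
})

test_that("the full builder trace on the 4-gene worked input", {
  g <- fixture("fig9_partition")
  s <- build_scenario(g)
  tr <- attr(s, "trace")
  expect_equal(tr$epsilon, 1)
  vt <- tr$vertices
  # top-level recursion root at tau_S(rho_S) + eps = 4, reconciled with the
  # planted species edge
  top <- vt[vt$role == "rho_prime", ][1, ]
  expect_equal(top$tau, 4)
  # vertex for the H2 component {a, b} at tau_S(rho_S) - eps = 2
  vj <- vt[vt$role == "v_j" & vt$members == "a,b", ]
  expect_equal(vj$tau, 2)
  # local root of the recursion into species leaf A on {a} at 0 + eps = 1
  leafrec <- vt[vt$role == "rho_prime" & vt$u_S == "A" & vt$members == "a", ]
  expect_equal(leafrec$tau, 1)
  expect_equal(vt[vt$role == "leaf" & vt$label == "a", "tau"], 0)
  # the output explains its input
  expect_true(partitions_equal(divergence_partition(s), g))
  expect_identical(tree_canonical(s$gene_tree), "((a',b'),(a,b))")
})

test_that("two same-colored genes: cherry above the species root edge", {
  v <- c("x1", "x2")
  sig <- stats::setNames(c("A", "A"), v)
  g <- partition_from_rel(v, sig, rbind(c("x1", "x2")), "GT")
  s <- build_scenario(g)
  expect_identical(tree_canonical(s$gene_tree), "(x1,x2)")
  rho <- s$gene_tree$labels[s$gene_tree$root]
  expect_length(s$mu[[rho]], 2)    # reconciled with the planted species edge
  expect_true(partitions_equal(divergence_partition(s), g))
})

test_that("single-gene input produces the one-leaf scenario", {
  v <- "x"
  sig <- stats::setNames("A", v)
  g <- partition_from_rel(v, sig, NULL, character(0))
  s <- build_scenario(g)
  expect_identical(tree_leaves(s$gene_tree), "x")
  expect_identical(nrow(validate_relaxed(s)), 0L)
})

test_that("round trip: built scenarios explain the partitions of simulations", {
  for (i in 1:40) {
    s <- random_scenario(3 + (i %% 4), 5 + (i %% 9),
                         transfer_prob = c(0, .15, .3, .45)[(i %% 4) + 1],
                         dup_prob = 0.25, seed = 1000 + i)
    g <- divergence_partition(s)
    expect_true(is_valid_input(g)$explainable)
    built <- build_scenario(g)
    expect_true(partitions_equal(divergence_partition(built), g))
    # relaxed-route outputs always satisfy S4 and S5
    v <- validate_restricted(built)
    expect_false(any(v$axiom %in% c("S4", "S5")))
  }
})

test_that("restricted construction satisfies S4-S6 and still explains", {
  for (i in 1:25) {
    s <- random_scenario(3 + (i %% 4), 5 + (i %% 7), transfer_prob = 0.3,
                         dup_prob = 0.25, seed = 1100 + i)
    g <- divergence_partition(s)
    built <- build_scenario(g, restricted = TRUE)
    expect_identical(nrow(validate_restricted(built)), 0L)
    expect_true(partitions_equal(divergence_partition(built), g))
  }
})

test_that("default choice on the traced input violates S6; restricted fixes it", {
  g <- fixture("fig9_partition")
  s1 <- build_scenario(g, restricted = FALSE)
  v1 <- validate_restricted(s1)
  expect_true("S6" %in% v1$axiom)
  s2 <- build_scenario(g, restricted = TRUE)
  expect_identical(nrow(validate_restricted(s2)), 0L)
})

test_that("EDT edges of the input map their gene lca onto the species lca", {
  for (i in 1:10) {
    s <- random_scenario(4, 8, transfer_prob = 0.3, seed = 1200 + i)
    g <- divergence_partition(s)
    built <- build_scenario(g)
    T <- built$gene_tree; S <- built$species_tree
    if (nrow(g$edt$edges) == 0) next
    for (r in seq_len(nrow(g$edt$edges))) {
      x <- g$edt$edges[r, 1]; y <- g$edt$edges[r, 2]
      m <- built$mu[[tree_lca(T, c(x, y))]]
      expect_identical(unname(m), tree_lca(S, c(g$sigma[[x]], g$sigma[[y]])))
    }
  }
})

test_that("a supplied agreeing species tree is used unchanged", {
  g <- fixture("fig9_partition")
  S <- read_newick("((A,B),Z);")   # extra, unused color is allowed
  s <- build_scenario(g, species_tree = S, restricted = TRUE)
  expect_identical(write_newick(s$species_tree), write_newick(S))
  expect_true(partitions_equal(divergence_partition(s), g))
  # a tree violating the triple system is rejected
  gp <- fixture("p4_partition")   # requires S = ((A,C),(B,D)) shape
  bad <- read_newick("((A,B),(C,D));")
  expect_error(build_scenario(gp, species_tree = bad), "does not agree")
})

test_that("invalid inputs are rejected with the failed condition named", {
  v <- c("p", "q", "r")
  sig_same <- stats::setNames(c("A", "A", "B"), v)
  # same-colored LDT edge
  g1 <- partition_from_rel(v, sig_same,
                           rbind(c("p", "q"), c("p", "r"), c("q", "r")),
                           c("LT", "GT", "GT"))
  expect_identical(is_valid_input(g1)$failed_condition, "proper_coloring_ldt")
  expect_error(build_scenario(g1), "proper_coloring_ldt")
  # same-colored EDT edge
  g2 <- partition_from_rel(v, sig_same,
                           rbind(c("p", "q"), c("p", "r"), c("q", "r")),
                           c("EQ", "GT", "GT"))
  expect_identical(is_valid_input(g2)$failed_condition, "proper_coloring_edt")
  # LDT P4
  v4 <- paste0("x", 1:4)
  sig4 <- stats::setNames(paste0("C", 1:4), v4)
  rel <- c("LT", "LT", "LT", "GT", "GT", "GT")
  prs <- rbind(c("x1", "x2"), c("x2", "x3"), c("x3", "x4"),
               c("x1", "x3"), c("x1", "x4"), c("x2", "x4"))
  g3 <- partition_from_rel(v4, sig4, prs, rel)
  expect_identical(is_valid_input(g3)$failed_condition, "cograph_ldt")
  # PDT P4 (with the complement placed in the EDT graph so the LDT side stays
  # an edgeless cograph)
  g4 <- partition_from_rel(v4, sig4, prs, c("GT", "GT", "GT", "EQ", "EQ", "EQ"))
  expect_identical(is_valid_input(g4)$failed_condition, "cograph_pdt")
  # inconsistent species triples: one LDT path forces AB|C, the other AC|B
  v5 <- c("y1", "y2", "y3", "z1", "z2", "z3")
  sig5 <- stats::setNames(c("A", "B", "C", "A", "C", "B"), v5)
  prs5 <- t(utils::combn(v5, 2))
  rel5 <- rep("GT", nrow(prs5))
  lt5 <- c("y1\ry3", "y2\ry3", "z1\rz3", "z2\rz3")
  keys5 <- edtgraph:::pair_key(prs5[, 1], prs5[, 2])
  rel5[keys5 %in% lt5] <- "LT"
  g5 <- partition_from_rel(v5, sig5, prs5, rel5)
  expect_identical(is_valid_input(g5)$failed_condition, "triples_inconsistent")
  expect_identical(is_valid_input(fixture("fig9_partition"))$failed_condition,
                   NULL)
})
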