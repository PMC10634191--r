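# Triple extraction (informative/forbidden), BUILD, and mixed-triple trees.

test_that("gene triples on worked configurations", {
  # PDT cherry forces the gene triple: ab' and bb' prior, ab not
  v <- c("a", "b", "b2")
  sig <- stats::setNames(c("A", "B", "B"), v)
  g <- partition_from_rel(v, sig,
                          rbind(c("a", "b2"), c("b", "b2"), c("a", "b")),
                          c("GT", "GT", "LT"))
  sys <- gene_triples(g)
  expect_true(paste("a", "b", "b2", sep = "|") %in% triple_df_keys(sys$required))

  # edgeless LDT and PDT produce no required gene triples
  g0 <- partition_from_rel(v, sig,
                           rbind(c("a", "b2"), c("b", "b2"), c("a", "b")),
                           c("EQ", "EQ", "EQ"))
  expect_identical(nrow(gene_triples(g0)$required), 0L)
  # ... but EQ paths produce forbidden triples
  g1 <- partition_from_rel(v, sig,
                           rbind(c("a", "b2"), c("b", "b2"), c("a", "b")),
                           c("EQ", "EQ", "GT"))
  fk <- triple_df_keys(gene_triples(g1)$forbidden)
  expect_setequal(fk, c(paste("a", "b2", "b", sep = "|"),
                        paste("b", "b2", "a", sep = "|")))
})

test_that("species triples on worked configurations", {
  # two LDT edges sharing a vertex force a species triple
  v <- c("b", "c", "d")
  sig <- stats::setNames(c("B", "C", "D"), v)
  g <- partition_from_rel(v, sig,
                          rbind(c("b", "c"), c("b", "d"), c("c", "d")),
                          c("LT", "LT", "GT"))
  expect_true(paste("C", "D", "B", sep = "|") %in%
                triple_df_keys(species_triples(g)$required))

  # a PDT edge with both cross pairs outside forces a species triple
  v2 <- c("a", "b2", "c")
  sig2 <- stats::setNames(c("A", "B", "C"), v2)
  g2 <- partition_from_rel(v2, sig2,
                           rbind(c("a", "b2"), c("a", "c"), c("b2", "c")),
                           c("GT", "LT", "LT"))
  expect_true(paste("A", "B", "C", sep = "|") %in%
                triple_df_keys(species_triples(g2)$required))

  # all-same-color input yields no species triples at all
  v3 <- c("x1", "x2", "x3")
  sig3 <- stats::setNames(rep("A", 3), v3)
  g3 <- partition_from_rel(v3, sig3, t(utils::combn(v3, 2)), rep("GT", 3))
  sys3 <- species_triples(g3)
  expect_identical(nrow(sys3$required), 0L)
  expect_identical(nrow(sys3$forbidden), 0L)
})

test_that("trees of simulated scenarios agree with their extracted triples", {
  for (i in 1:15) {
    s <- random_scenario(4, 8, transfer_prob = 0.35, dup_prob = 0.25,
                         seed = 500 + i)
    g <- divergence_partition(s)
    expect_true(agrees(s$gene_tree, gene_triples(g)))
    expect_true(agrees(s$species_tree, species_triples(g)))
  }
})

test_that("triple systems of restrictions are subsets of the full systems", {
  for (i in 1:8) {
    s <- random_scenario(4, 9, transfer_prob = 0.3, seed = 540 + i)
    g <- divergence_partition(s)
    sub <- restrict_partition(g, sample(g$vertices, 6))
    full_s <- species_triples(g); part_s <- species_triples(sub)
    expect_true(all(triple_df_keys(part_s$required) %in%
                      triple_df_keys(full_s$required)))
    expect_true(all(triple_df_keys(part_s$forbidden) %in%
                      triple_df_keys(full_s$forbidden)))
  }
})

test_that("BUILD on examples", {
  r1 <- triple_df_make("A", "B", "C")
  t1 <- aho_build(r1, c("A", "B", "C"))
  expect_identical(tree_canonical(t1), "((A,B),C)")
  r2 <- rbind(triple_df_make("A", "B", "C"), triple_df_make("A", "C", "B"))
  expect_null(aho_build(r2, c("A", "B", "C")))
  # free labels attach at the root
  t3 <- aho_build(r1, c("A", "B", "C", "D"))
  expect_identical(tree_canonical(t3), "((A,B),C,D)")
})

test_that("BUILD consistency matches exhaustive search on random triple sets", {
  labs <- c("A", "B", "C", "D", "E")
  trees <- enumerate_rooted_trees(labs)
  tabs <- lapply(trees, displayed_triple_keys, labels = labs)
  set.seed(11)
  for (rep in 1:60) {
    k <- sample(1:5, 1)
    R <- do.call(rbind, lapply(seq_len(k), function(j) {
      t <- sample(labs, 3)
      triple_df_make(t[1], t[2], t[3])
    }))
    built <- aho_build(R, labs)
    want <- triple_df_keys(edtgraph:::triple_df(R$a, R$b, R$out))
    oracle_ok <- any(vapply(tabs, function(keys) all(want %in% keys), logical(1)))
    expect_identical(!is.null(built), oracle_ok)
    if (!is.null(built)) {
      for (w in want) {
        p <- strsplit(w, "|", fixed = TRUE)[[1]]
        expect_true(tree_displays(built, rooted_triple(p[1], p[2], p[3])))
      }
    }
  }
})

test_that("mixed trees on examples", {
  labs <- c("A", "B", "C")
  none <- triple_df_make(character(0), character(0), character(0))
  all3 <- rbind(triple_df_make("A", "B", "C"), triple_df_make("A", "C", "B"),
                triple_df_make("B", "C", "A"))
  star <- mixed_tree(none, all3, labs)
  expect_identical(tree_canonical(star), "(A,B,C)")
  expect_null(mixed_tree(triple_df_make("A", "B", "C"),
                         triple_df_make("A", "B", "C"), labs))
})

test_that("mixed trees match exhaustive enumeration on random systems", {
  labs <- c("A", "B", "C", "D", "E", "F")
  trees <- enumerate_rooted_trees(labs)
  tabs <- lapply(trees, displayed_triple_keys, labels = labs)
  set.seed(12)
  n_sys <- 150
  for (rep in seq_len(n_sys)) {
    mk <- function(k) {
      if (k == 0) return(triple_df_make(character(0), character(0), character(0)))
      do.call(rbind, lapply(seq_len(k), function(j) {
        t <- sample(labs, 3)
        triple_df_make(t[1], t[2], t[3])
      }))
    }
    R <- mk(sample(0:4, 1)); F <- mk(sample(0:4, 1))
    built <- mixed_tree(R, F, labs)
    rk <- triple_df_keys(edtgraph:::triple_df(R$a, R$b, R$out))
    fk <- triple_df_keys(edtgraph:::triple_df(F$a, F$b, F$out))
    oracle_ok <- any(vapply(tabs, function(keys) {
      all(rk %in% keys) && !any(fk %in% keys)
    }, logical(1)))
    expect_identical(!is.null(built), oracle_ok)
    if (!is.null(built)) {
      expect_true(agrees(built, triple_system(R, F, labs)))
    }
  }
})

test_that("BUILD and mixed construction coincide on empty forbidden sets", {
  labs <- c("A", "B", "C", "D", "E")
  none <- triple_df_make(character(0), character(0), character(0))
  set.seed(13)
  for (rep in 1:40) {
    k <- sample(1:5, 1)
    R <- do.call(rbind, lapply(seq_len(k), function(j) {
      t <- sample(labs, 3)
      triple_df_make(t[1], t[2], t[3])
    }))
    expect_identical(is.null(aho_build(R, labs)),
                     is.null(mixed_tree(R, none, labs)))
  }
})

test_that("agrees on examples", {
  t <- read_newick("((A,B),C);")
  sys <- triple_system(triple_df_make("A", "B", "C"),
                       triple_df_make("A", "C", "B"), c("A", "B", "C"))
  expect_true(agrees(t, sys))
  star <- read_newick("(A,B,C);")
  sys2 <- triple_system(triple_df_make(character(0), character(0), character(0)),
                        rbind(triple_df_make("A", "B", "C"),
                              triple_df_make("A", "C", "B")), c("A", "B", "C"))
  expect_true(agrees(star, sys2))
  expect_false(agrees(star, sys))
})
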