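# The divergence-time 3-partition of a scenario.

#' Divergence-time partition of a scenario
#'
#' For every pair of gene leaves x, y the stamp of their gene-tree last
#' common ancestor is compared with the stamp of the species-tree last
#' common ancestor of their colors: later divergence (LDT, gene stamp
#' smaller), equal divergence (EDT) or prior divergence (PDT, gene stamp
#' larger).  The three edge sets partition all unordered pairs.
#'
#' @param s an `edt_scenario`.
#' @param tol time tolerance, see [edt_tol()].
#' @return a `three_partition` on the gene leaves, colored by `sigma`.
#' @export
divergence_partition <- function(s, tol = edt_tol()) {
  T <- s$gene_tree; S <- s$species_tree
  leaves <- sort(tree_leaves(T), method = "radix")
  n <- length(leaves)
  if (n < 1) stop("scenario without gene leaves")
  pairs <- matrix(character(0), ncol = 2)
  rel <- character(0)
  if (n >= 2) {
    pairs <- t(utils::combn(leaves, 2))
    rel <- character(nrow(pairs))
    for (r in seq_len(nrow(pairs))) {
      x <- pairs[r, 1]; y <- pairs[r, 2]
      tg <- s$tau_T[[tree_lca(T, c(x, y))]]
      ts <- s$tau_S[[tree_lca(S, c(s$sigma[[x]], s$sigma[[y]]))]]
      rel[r] <- switch(as.character(time_cmp(tg, ts, tol)),
                       "-1" = "LT", "0" = "EQ", "1" = "GT")
    }
  }
  partition_from_rel(leaves, s$sigma, pairs, rel)
}
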