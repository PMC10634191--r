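# Plain-text interchange formats.
#
# Colored graphs / 3-partitions travel as TSV: a header block of lines
# "#color<TAB>vertex<TAB>color" followed by one edge per line
# "u<TAB>v<TAB>{LT|EQ|GT}" (the class column is optional for single graphs).
# Scenarios travel as a JSON bundle with Newick trees carrying explicit
# internal vertex ids, so the reconciliation map is unambiguous.

#' Write / read a graph 3-partition as TSV
#'
#' The file lists every unordered vertex pair with its class; partial files
#' are rejected because a 3-partition must cover all pairs.
#'
#' @param g a `three_partition`.
#' @param path file path.
#' @return `read_partition_tsv` returns a `three_partition`;
#'   `write_partition_tsv` returns `path` invisibly.
#' @export
write_partition_tsv <- function(g, path) {
  stopifnot(inherits(g, "three_partition"))
  con <- file(path, "w")
  on.exit(close(con))
  for (v in g$vertices) {
    cat("#color\t", v, "\t", g$sigma[[v]], "\n", sep = "", file = con)
  }
  keys <- names(g$rel)
  parts <- strsplit(keys, "\r", fixed = TRUE)
  for (i in seq_along(keys)) {
    cat(parts[[i]][1], "\t", parts[[i]][2], "\t", g$rel[[i]], "\n",
        sep = "", file = con)
  }
  invisible(path)
}

.read_graph_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  sigma <- character(0)
  edges <- list()
  for (i in seq_along(lines)) {
    line <- trimws(lines[i])
    if (!nzchar(line) || line == "#colors") next
    f <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (f[1] == "#color") {
      if (length(f) != 3) stop("line ", i, ": expected '#color\\tvertex\\tcolor'")
      sigma[f[2]] <- f[3]
    } else if (startsWith(f[1], "#")) {
      next
    } else {
      if (length(f) < 2) stop("line ", i, ": expected 'u\\tv[\\tclass]'")
      edges[[length(edges) + 1L]] <- f
    }
  }
  list(sigma = sigma, edges = edges)
}

#' @rdname write_partition_tsv
#' @export
read_partition_tsv <- function(path) {
  raw <- .read_graph_lines(path)
  if (length(raw$sigma) == 0) stop("no '#color' header lines found")
  bad <- which(lengths(raw$edges) != 3)
  if (length(bad) > 0) stop("pair records must carry a class LT/EQ/GT")
  pairs <- do.call(rbind, lapply(raw$edges, function(f) f[1:2]))
  rel <- vapply(raw$edges, `[`, character(1), 3)
  if (!all(rel %in% c("LT", "EQ", "GT"))) {
    stop("unknown pair class: ", paste(setdiff(rel, c("LT", "EQ", "GT")),
                                       collapse = ", "))
  }
  partition_from_rel(names(raw$sigma), raw$sigma, pairs, rel)
}

#' Write / read a single colored graph as TSV
#'
#' Same header block as the partition format; edge lines carry just the two
#' endpoints (a third column, if present, is ignored).
#'
#' @param g a `colored_graph`.
#' @param path file path.
#' @return `read_colored_graph_tsv` returns a `colored_graph`;
#'   the writer returns `path` invisibly.
#' @export
write_colored_graph_tsv <- function(g, path) {
  stopifnot(inherits(g, "colored_graph"))
  con <- file(path, "w")
  on.exit(close(con))
  for (v in g$vertices) {
    cat("#color\t", v, "\t", g$sigma[[v]], "\n", sep = "", file = con)
  }
  for (r in seq_len(nrow(g$edges))) {
    cat(g$edges[r, 1], "\t", g$edges[r, 2], "\n", sep = "", file = con)
  }
  invisible(path)
}

#' @rdname write_colored_graph_tsv
#' @export
read_colored_graph_tsv <- function(path) {
  raw <- .read_graph_lines(path)
  if (length(raw$sigma) == 0) stop("no '#color' header lines found")
  edges <- if (length(raw$edges) == 0) NULL else {
    do.call(rbind, lapply(raw$edges, function(f) f[1:2]))
  }
  colored_graph(names(raw$sigma), edges, raw$sigma)
}

#' Serialize / deserialize a scenario as a JSON bundle
#'
#' Trees are stored as Newick strings with explicit internal vertex ids plus
#' the planted-root id; `mu` maps vertex ids to a vertex id or a
#' `[parent, child]` edge; time maps are id -> number.  The round trip is
#' lossless.
#'
#' @param s an `edt_scenario`.
#' @param path file path.
#' @return `read_scenario_json` returns an `edt_scenario`; the writer
#'   returns `path` invisibly.
#' @export
write_scenario_json <- function(s, path) {
  stopifnot(inherits(s, "edt_scenario"))
  T <- s$gene_tree; S <- s$species_tree
  tree_rec <- function(t) {
    list(newick = write_newick(t, internal_ids = TRUE),
         planted_root = t$labels[t$planted_root],
         parent = as.list(stats::setNames(
           ifelse(is.na(t$parent), NA_character_, t$labels[t$parent]), t$labels)),
         children_order = {
           co <- stats::setNames(
             lapply(seq_along(t$labels), function(i) t$labels[t$children[[i]]]),
             t$labels)
           co[lengths(co) > 0]
         })
  }
  bundle <- list(
    gene_tree = tree_rec(T),
    species_tree = tree_rec(S),
    sigma = as.list(s$sigma),
    mu = lapply(s$mu, function(m) if (length(m) == 2) as.list(m) else m),
    tau_T = as.list(s$tau_T),
    tau_S = as.list(s$tau_S))
  jsonlite::write_json(bundle, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

.read_planted_json <- function(rec) {
  if (!is.null(rec$parent)) {
    p <- vapply(rec$parent, function(x) if (is.null(x)) NA_character_ else x,
                character(1))
    ord <- lapply(rec$children_order, function(x) unlist(x))
    return(planted_tree(p, children_order = ord))
  }
  # legacy/hand-written bundles: Newick with ids plus a planted-root label
  read_newick(rec$newick, keep_internal_ids = TRUE)
}

#' @rdname write_scenario_json
#' @export
read_scenario_json <- function(path) {
  b <- jsonlite::read_json(path)
  if (is.null(b$gene_tree) || is.null(b$species_tree)) {
    stop("scenario bundle must contain 'gene_tree' and 'species_tree'")
  }
  T <- .read_planted_json(b$gene_tree)
  S <- .read_planted_json(b$species_tree)
  mu <- lapply(b$mu, function(m) unlist(m))
  scenario(T, S, unlist(b$sigma), mu, unlist(b$tau_T), unlist(b$tau_S))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
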