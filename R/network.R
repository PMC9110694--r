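#' Build a Spearman correlation network over selected metabolites
#'
#' All pairwise Spearman correlations between features are tested
#' (tie-corrected, asymptotic two-sided P); P-values are Bonferroni-adjusted
#' with the number of tested pairs m(m-1)/2 as denominator, and an edge is
#' kept iff the adjusted P is at or below `threshold`. Edge weight is
#' |rho|; the correlation sign is retained as an edge attribute. The edge
#' set is deterministic given the input matrix.
#'
#' @param X_sel Sample x feature matrix of the selected metabolites.
#' @param threshold Bonferroni-adjusted P-value cutoff (inclusive).
#' @param labels Optional named vector of node labels (e.g. "term-only",
#'   "preterm-only", "both") keyed by feature id.
#' @return An [igraph][igraph::igraph-package] undirected graph with vertex
#'   attributes `name`, `label` and edge attributes `rho`, `weight`
#'   (= |rho|), `sign`, `p_adj`.
#' @export
build_network <- function(X_sel, threshold = 0.01, labels = NULL) {
  X_sel <- as.matrix(X_sel)
  m <- ncol(X_sel)
  if (m < 2L) stop("need at least 2 features to build a network")
  ids <- colnames(X_sel)
  if (is.null(ids)) ids <- colnames(X_sel) <- sprintf("f%04d", seq_len(m))
  n_pairs <- m * (m - 1) / 2
  edges <- list()
  for (i in seq_len(m - 1L)) {
    for (j in seq(i + 1L, m)) {
      if (stats::sd(X_sel[, i]) == 0 || stats::sd(X_sel[, j]) == 0) next
      ct <- suppressWarnings(stats::cor.test(X_sel[, i], X_sel[, j],
                                             method = "spearman",
                                             exact = FALSE))
      p_adj <- min(1, ct$p.value * n_pairs)
      if (p_adj <= threshold)
        edges[[length(edges) + 1L]] <-
          data.frame(from = ids[i], to = ids[j],
                     rho = unname(ct$estimate), p_adj = p_adj,
                     stringsAsFactors = FALSE)
    }
  }
  edf <- if (length(edges)) do.call(rbind, edges) else
    data.frame(from = character(), to = character(), rho = numeric(),
               p_adj = numeric())
  g <- igraph::graph_from_data_frame(edf, directed = FALSE,
                                     vertices = data.frame(name = ids))
  igraph::E(g)$weight <- abs(igraph::E(g)$rho)
  igraph::E(g)$sign <- sign(igraph::E(g)$rho)
  igraph::V(g)$label <- if (!is.null(labels))
    unname(labels[igraph::V(g)$name]) else NA_character_
  g
}

#' Betweenness centrality of network nodes
#'
#' Shortest-path betweenness (Brandes' algorithm), unnormalized. By default
#' paths are unweighted for determinism; with `weighted = TRUE` edge
#' distances are 1/|rho| so strong correlations make short paths.
#'
#' @param graph Graph from [build_network()].
#' @param weighted Use 1/|rho| edge distances.
#' @return Named numeric vector of per-node betweenness.
#' @export
betweenness_centrality <- function(graph, weighted = FALSE) {
  if (igraph::vcount(graph) == 0L) return(stats::setNames(numeric(), character()))
  w <- if (weighted) 1 / igraph::E(graph)$weight else NA
  igraph::betweenness(graph, directed = FALSE, weights = w,
                      normalized = FALSE)
}

#' Seeded Fruchterman-Reingold layout
#'
#' @param graph Graph from [build_network()].
#' @param seed Integer seed; identical seeds give identical coordinates.
#' @return Numeric matrix (nodes x 2) of coordinates, rownames = node ids.
#' @export
layout_fr <- function(graph, seed = 1L) {
  n <- igraph::vcount(graph)
  if (n == 0L) return(matrix(numeric(), ncol = 2L))
  if (n == 1L)
    return(matrix(0, nrow = 1L, ncol = 2L,
                  dimnames = list(igraph::V(graph)$name, c("x", "y"))))
  set.seed(seed)
  xy <- igraph::layout_with_fr(graph)
  dimnames(xy) <- list(igraph::V(graph)$name, c("x", "y"))
  xy
}

#' Export a correlation network to plain-text formats
#'
#' Writes GraphML, an edge-list TSV (source, target, rho, p_adj) and a node
#' table CSV (id, label, betweenness, x, y).
#'
#' @param graph Graph from [build_network()].
#' @param dir Output directory.
#' @param seed Layout seed.
#' @return Invisibly, the written paths.
#' @export
write_network <- function(graph, dir, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gml <- file.path(dir, "network.graphml")
  igraph::write_graph(graph, gml, format = "graphml")
  edf <- igraph::as_data_frame(graph, what = "edges")
  ep <- file.path(dir, "edges.tsv")
  utils::write.table(edf[, c("from", "to", "rho", "p_adj")], ep, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  xy <- layout_fr(graph, seed)
  btw <- betweenness_centrality(graph)
  nodes <- data.frame(id = igraph::V(graph)$name,
                      label = igraph::V(graph)$label,
                      betweenness = unname(btw[igraph::V(graph)$name]),
                      x = xy[, 1], y = xy[, 2], row.names = NULL)
  np <- file.path(dir, "nodes.csv")
  utils::write.csv(nodes, np, row.names = FALSE)
  invisible(c(graphml = gml, edges = ep, nodes = np))
}
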