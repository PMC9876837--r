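# Seed-gene subnetwork construction from an interaction edge list, degree
# and betweenness centralities, hub ranking, and bipartite gene-entity
# reports (gene-disease associations, TF-target interactions).

#' Build a seed-gene subnetwork
#'
#' Filters the interactome at `min_score` and extracts either the
#' first-order network (seed genes plus all their direct interactors, with
#' every edge among included nodes; non-seed interactors appear as
#' "connector" nodes) or the zero-order network (induced subgraph on the
#' seeds only). Seeds present in the interactome but isolated after
#' filtering are retained and flagged.
#'
#' @param seeds character vector of seed gene symbols (e.g. DEGs).
#' @param edges interactome `data.frame` (`node_a`, `node_b`, `score` in
#'   `[0, 1]`), see [readEdgeList()].
#' @param min_score minimum interaction confidence retained (default 0.9,
#'   STRING-style highest confidence).
#' @param order `"first"` (default) or `"zero"`.
#' @return an [InteractionNetwork-class].
#' @export
buildSubnetwork <- function(seeds, edges, min_score = 0.9,
                            order = c("first", "zero")) {
  order <- match.arg(order)
  if (any(edges$score < 0 | edges$score > 1)) {
    stop("edge scores must lie in [0, 1]")
  }
  seeds <- unique(seeds)
  interactome_nodes <- unique(c(edges$node_a, edges$node_b))
  present <- intersect(seeds, interactome_nodes)
  if (length(present) == 0L) {
    stop("none of the seed genes is present in the interactome")
  }
  if (length(present) < length(seeds)) {
    .msg("%d of %d seeds absent from the interactome",
         length(seeds) - length(present), length(seeds))
  }
  kept <- edges[edges$score >= min_score, , drop = FALSE]
  g0 <- igraph::graph_from_data_frame(
    kept[, c("node_a", "node_b")], directed = FALSE,
    vertices = data.frame(name = interactome_nodes))
  igraph::E(g0)$score <- kept$score
  g0 <- igraph::simplify(g0, edge.attr.comb = "max")
  include <- if (order == "first") {
    nb <- igraph::adjacent_vertices(g0, present)
    unique(c(present, unlist(lapply(nb, names), use.names = FALSE)))
  } else {
    present
  }
  g <- igraph::induced_subgraph(g0, include)
  deg <- igraph::degree(g)
  nodes <- S4Vectors::DataFrame(
    gene = igraph::V(g)$name,
    is_seed = igraph::V(g)$name %in% seeds,
    isolated = deg == 0)
  if (any(nodes$isolated & nodes$is_seed)) {
    .msg("%d isolated seeds retained", sum(nodes$isolated & nodes$is_seed))
  }
  methods::new("InteractionNetwork", graph = g, nodes = nodes)
}

#' Compute node centralities
#'
#' Fills the node table with the exact degree and the Brandes betweenness
#' centrality of the unweighted undirected graph (unnormalized source-target
#' pair counts, endpoints excluded); interaction scores act as a
#' construction filter only and do not weight shortest paths.
#'
#' @param network an [InteractionNetwork-class].
#' @return the network with `degree` and `betweenness` node columns.
#' @export
addCentralities <- function(network) {
  stopifnot(methods::is(network, "InteractionNetwork"))
  g <- network@graph
  if (igraph::vcount(g) == 0L) stop("empty network")
  nodes <- network@nodes
  nodes$degree <- unname(igraph::degree(g))
  nodes$betweenness <- unname(igraph::betweenness(g, directed = FALSE,
                                                  weights = NA,
                                                  normalized = FALSE))
  methods::initialize(network, nodes = nodes)
}

#' Rank hub genes
#'
#' Top-`k` nodes by degree, ties broken by betweenness then
#' lexicographically by symbol, optionally joined with differential-
#' expression columns and metagene assignment.
#'
#' @param network an [InteractionNetwork-class] with centralities (see
#'   [addCentralities()]).
#' @param k number of hubs (default 10); if larger than the node count,
#'   all nodes are returned with a warning.
#' @param deg_table optional DEG table ([moderatedT()]) to join
#'   `mean_expr` and `logFC`.
#' @param metagenes optional [MetageneSet-class] to join the metagene
#'   assignment.
#' @return a [S4Vectors::DataFrame] of hubs sorted by the ranking.
#' @export
rankHubs <- function(network, k = 10L, deg_table = NULL, metagenes = NULL) {
  stopifnot(methods::is(network, "InteractionNetwork"))
  nodes <- network@nodes
  if (!all(c("degree", "betweenness") %in% colnames(nodes))) {
    stop("run addCentralities() first")
  }
  if (k > nrow(nodes)) {
    warning("k exceeds the node count; returning all nodes")
    k <- nrow(nodes)
  }
  o <- order(-nodes$degree, -nodes$betweenness, nodes$gene)
  hubs <- nodes[o[seq_len(k)], c("gene", "is_seed", "degree", "betweenness")]
  if (!is.null(deg_table)) {
    i <- match(hubs$gene, deg_table$gene)
    hubs$mean_expr <- deg_table$mean_expr[i]
    hubs$logFC <- deg_table$logFC[i]
  }
  if (!is.null(metagenes)) {
    mem <- memberTable(metagenes)
    i <- match(hubs$gene, mem$gene)
    hubs$metagene <- mem$metagene[i]
  }
  rownames(hubs) <- NULL
  hubs
}

#' Bipartite gene-entity report
#'
#' Filters a gene-entity association table (gene-disease or TF-target) to
#' the query genes and `min_score`, and reports every entity connected to
#' at least `min_shared` query genes together with its gene list. With
#' `rank_by_centrality = TRUE` (TF convention) entities are additionally
#' ranked by degree then betweenness on the bipartite graph.
#'
#' @param genes query gene symbols.
#' @param assoc association `data.frame` (`gene`, `entity`, `score`), see
#'   [readAssociation()].
#' @param min_score minimum association score (default 0).
#' @param min_shared minimum number of distinct query genes per reported
#'   entity (default 2).
#' @param rank_by_centrality rank entities by bipartite degree and
#'   betweenness instead of gene count alone.
#' @return a [S4Vectors::DataFrame] with columns `entity`, `n_genes`,
#'   `genes` (comma-separated) and, when ranked by centrality, `degree`
#'   and `betweenness`.
#' @export
bipartiteReport <- function(genes, assoc, min_score = 0, min_shared = 2L,
                            rank_by_centrality = FALSE) {
  genes <- unique(genes)
  hit <- assoc[assoc$gene %in% genes & assoc$score >= min_score, ,
               drop = FALSE]
  hit <- unique(hit[, c("gene", "entity")])
  if (nrow(hit) == 0L) {
    return(S4Vectors::DataFrame(entity = character(), n_genes = integer(),
                                genes = character()))
  }
  counts <- table(hit$entity)
  keep <- names(counts)[counts >= min_shared]
  hit <- hit[hit$entity %in% keep, , drop = FALSE]
  if (nrow(hit) == 0L) {
    return(S4Vectors::DataFrame(entity = character(), n_genes = integer(),
                                genes = character()))
  }
  out <- S4Vectors::DataFrame(
    entity = keep,
    n_genes = as.integer(counts[keep]),
    genes = vapply(keep, function(e) {
      paste(sort(hit$gene[hit$entity == e]), collapse = ",")
    }, "", USE.NAMES = FALSE))
  if (rank_by_centrality) {
    g <- igraph::graph_from_data_frame(hit[, c("gene", "entity")],
                                       directed = FALSE)
    bc <- igraph::betweenness(g, directed = FALSE, weights = NA)
    dg <- igraph::degree(g)
    out$degree <- as.integer(dg[out$entity])
    out$betweenness <- unname(bc[out$entity])
    out <- out[order(-out$degree, -out$betweenness, out$entity), ]
  } else {
    out <- out[order(-out$n_genes, out$entity), ]
  }
  rownames(out) <- NULL
  out
}
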