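# Similarity network (>50% edges) and UPGMA dendrogram over the
# non-redundant catalogue. The network is the deorphanization map: known
# producers connected to orphans suggest chemotypes; singletons are the
# unexplored diversity.

#' Build the cluster similarity network
#'
#' Undirected simple graph with one node per cluster and an edge iff the
#' pairwise score is *strictly* greater than `threshold`, weighted by the
#' score. No self-edges.
#'
#' @param matrix Similarity matrix (validated).
#' @param threshold Edge threshold in percent (default 50).
#' @param node_attrs Optional data frame with a `cluster_id` column plus
#'   attribute columns (e.g. `pks_type`, `known_product`, `phylum`)
#'   attached to nodes.
#' @return An [igraph::graph] object.
#' @export
build_network <- function(matrix, threshold = 50, node_attrs = NULL) {
  validate_similarity_matrix(matrix)
  if (threshold >= 100)
    warning("build_network: threshold >= 100 yields an edgeless graph")
  ids <- rownames(matrix)
  g <- igraph::make_empty_graph(n = length(ids), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = ids)
  if (length(ids) > 1L) {
    idx <- which(upper.tri(matrix) & matrix > threshold, arr.ind = TRUE)
    if (nrow(idx)) {
      edges <- rbind(ids[idx[, 1]], ids[idx[, 2]])
      g <- igraph::add_edges(g, as.vector(edges),
                             weight = matrix[idx])
    }
  }
  if (!is.null(node_attrs)) {
    stopifnot("cluster_id" %in% names(node_attrs))
    at <- node_attrs[match(ids, node_attrs$cluster_id), , drop = FALSE]
    for (col in setdiff(names(node_attrs), "cluster_id"))
      g <- igraph::set_vertex_attr(g, col, value = at[[col]])
  }
  g
}

#' Connected components and disconnected singletons
#'
#' Partitions the network nodes; singleton components are additionally
#' reported as `disconnected` -- the orphan assembly lines not connected
#' to any other cluster.
#'
#' @param graph Graph from [build_network()].
#' @return List with `components` (list of sorted id vectors, largest
#'   first) and `disconnected` (sorted ids of singletons).
#' @export
connected_components <- function(graph) {
  comp <- igraph::components(graph)
  members <- split(igraph::V(graph)$name, comp$membership)
  members <- lapply(members, sort)
  members <- members[order(-vapply(members, length, integer(1)),
                           vapply(members, `[`, "", 1L))]
  names(members) <- NULL
  singles <- sort(unlist(members[vapply(members, length, integer(1)) == 1L]))
  list(components = members,
       disconnected = if (is.null(singles)) character(0) else singles)
}

#' Export the similarity network
#'
#' @param graph Graph from [build_network()].
#' @param path Output file.
#' @param format `"graphml"` (typed attributes, Cytoscape-consumable),
#'   `"sif"` (`idA sim idB` lines; isolated nodes as bare ids) or
#'   `"edge_tsv"` (`from  to  weight`).
#' @return `path`, invisibly.
#' @export
export_network <- function(graph, path, format = c("graphml", "sif", "edge_tsv")) {
  format <- match.arg(format)
  ord <- order(igraph::V(graph)$name)
  graph <- igraph::permute(graph, order(ord))  # deterministic node order
  if (format == "graphml") {
    igraph::write_graph(graph, path, format = "graphml")
  } else if (format == "sif") {
    e <- igraph::as_edgelist(graph)
    lines <- character(0)
    if (nrow(e)) lines <- paste(e[, 1], "sim", e[, 2])
    deg <- igraph::degree(graph)
    lines <- c(lines, igraph::V(graph)$name[deg == 0])
    writeLines(lines, path)
  } else {
    e <- igraph::as_edgelist(graph)
    df <- data.frame(from = e[, 1], to = e[, 2],
                     weight = if (nrow(e))
                       format_num(igraph::E(graph)$weight, 6) else numeric(0))
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a network written by [export_network()]
#'
#' @param path File path.
#' @param format `"graphml"` or `"edge_tsv"`.
#' @return An igraph graph.
#' @export
read_network <- function(path, format = c("graphml", "edge_tsv")) {
  format <- match.arg(format)
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    # igraph stores the name attribute verbatim; nothing else to do
    return(g)
  }
  df <- read.delim(path, stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(df, directed = FALSE)
}

#' UPGMA dendrogram of the catalogue
#'
#' Average-linkage agglomeration on the distance `d = 100 - similarity`,
#' returned as an `ape::phylo` tree with the cluster ids as leaves.
#' Serialize with [write_dendrogram()] (Newick with branch lengths).
#'
#' @param matrix Similarity matrix over >= 2 clusters.
#' @return An `ape::phylo` object (ultrametric).
#' @export
build_dendrogram <- function(matrix) {
  validate_similarity_matrix(matrix)
  if (nrow(matrix) < 2L)
    stop("build_dendrogram: need at least two clusters")
  d <- as.dist(100 - matrix)
  ape::as.phylo(hclust(d, method = "average"))
}

#' @rdname build_dendrogram
#' @param tree `phylo` tree from [build_dendrogram()].
#' @param path Output Newick file.
#' @export
write_dendrogram <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
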