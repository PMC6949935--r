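#' Write a network to disk
#'
#' The edge-list format is a tab-delimited table (source, target, weight,
#' sign, same_module) that graph tools import directly; GraphML additionally
#' carries the module id and phylum as node attributes.
#'
#' @param net an `eco_network`.
#' @param path output path.
#' @param format `"edgelist"` (TSV) or `"graphml"`.
#' @param partition optional `module_partition` for the module annotations.
#' @export
write_network <- function(net, path, format = c("edgelist", "graphml"),
                          partition = NULL) {
  format <- match.arg(format)
  if (format == "edgelist") {
    edges <- net$edges
    edges$weight <- signif(edges$weight, 6)
    edges$same_module <- if (!is.null(partition))
      as.integer(partition$membership[edges$source] ==
                   partition$membership[edges$target])
    else NA_integer_
    utils::write.table(edges, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    g <- net$graph
    if (!is.null(partition))
      igraph::V(g)$module <- as.integer(partition$membership[net$nodes])
    if (!is.null(net$node_taxa))
      igraph::V(g)$phylum <- unname(net$node_taxa[net$nodes])
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Read a network back from an edge list written by [write_network()]
#'
#' @param path path to the TSV edge list.
#' @param threshold the similarity cutoff to record on the object.
#' @return an `eco_network` (without taxonomy).
#' @export
read_network_edgelist <- function(path, threshold) {
  edges <- utils::read.table(path, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE)
  nodes <- sort(unique(c(edges$source, edges$target)))
  g <- igraph::graph_from_data_frame(
    edges[, c("source", "target", "weight", "sign")],
    directed = FALSE, vertices = data.frame(name = nodes))
  structure(list(nodes = nodes,
                 edges = edges[, c("source", "target", "weight", "sign")],
                 graph = g, threshold = threshold, node_taxa = NULL),
            class = "eco_network")
}
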