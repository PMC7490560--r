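#' Export the interaction network to Cytoscape-readable files
#'
#' Writes the affinity-weighted binary interaction network as GraphML
#' (node attributes: annotation, functional class, conditional class,
#' known-partner flag; edge attributes: weight and evidence), as SIF with
#' relationship type `pp`, or as plain node/edge TSV tables. GraphML
#' export/import round trips preserve all nodes, edges and attributes.
#'
#' @param records An [integrate_evidence()] result.
#' @param edges A [compute_edge_weights()] result.
#' @param path Output file path. For `format = "tsv"` two files are
#'   written: `<path>_nodes.tsv` and `<path>_edges.tsv`.
#' @param format One of `"graphml"`, `"sif"`, `"tsv"`.
#' @param hub Hub node name (must match the `from` column of `edges`).
#' @return Invisibly, the path(s) written.
#' @export
export_network <- function(records, edges, path,
                           format = c("graphml", "sif", "tsv"),
                           hub = "NRF2") {
  if (!is.character(format) || !all(format %in% c("graphml", "sif", "tsv"))) {
    stop("export_network: unknown format; supported: graphml, sif, tsv")
  }
  format <- match.arg(format)
  stopifnot(inherits(records, "interaction_records"), is.data.frame(edges))

  nodes <- data.frame(
    name = c(hub, records$partner),
    annotation = c("hub", .na_str(records$annotation)),
    functional_class = c("hub", .na_str(records$functional_class)),
    conditional_class = c("hub", .na_str(records$conditional_class)),
    known_partner = c(TRUE, records$known_partner %in% TRUE),
    stringsAsFactors = FALSE
  )

  if (format == "graphml") {
    g <- igraph::graph_from_data_frame(
      edges[c("from", "to", "weight", "evidence", "degenerate")],
      directed = FALSE, vertices = nodes)
    igraph::write_graph(g, path, format = "graphml")
    return(invisible(path))
  }
  if (format == "sif") {
    lines <- sprintf("%s\tpp\t%s", edges$from, edges$to)
    writeLines(lines, path)
    return(invisible(path))
  }
  node_path <- paste0(path, "_nodes.tsv")
  edge_path <- paste0(path, "_edges.tsv")
  utils::write.table(nodes, node_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(edges, edge_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(node_path, edge_path))
}

.na_str <- function(x) {
  x <- as.character(x)
  x[is.na(x)] <- "absent"
  x
}

#' Read back a GraphML network export
#'
#' @param path GraphML file written by [export_network()].
#' @return An igraph graph with the exported node and edge attributes.
#' @export
read_network_graphml <- function(path) {
  igraph::read_graph(path, format = "graphml")
}
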