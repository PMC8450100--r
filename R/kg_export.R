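# Graph serialization: JSON dialect, GraphML, protein-centric TSV and the
# per-component query report.

#' Write a knowledge graph as JSON
#'
#' Serializes the canonical graph as a JSON object with `nodes` and
#' `edges` arrays plus the resolved query and a census. The output is
#' byte-stable for a given graph, so repeated builds with one seed can be
#' compared file-to-file.
#'
#' @param graph a `kg_graph`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
kg_write_json <- function(graph, path) {
  g <- kg_canonicalize(graph)
  obj <- list(
    nodes = g$nodes,
    edges = g$edges,
    query = g$query,
    census = graph_statistics(g)
  )
  if (!is.null(g$layout)) obj$layout <- g$layout
  jsonlite::write_json(obj, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA, na = "null", pretty = TRUE)
  invisible(path)
}

#' Read a knowledge graph written by [kg_write_json()]
#'
#' @param path a JSON graph file.
#' @return a `kg_graph` (query and census restored; params are not
#'   serialized).
#' @export
kg_read_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  g <- new_kg_graph()
  nodes <- as.data.frame(obj$nodes, stringsAsFactors = FALSE)
  edges <- as.data.frame(obj$edges, stringsAsFactors = FALSE)
  if (nrow(nodes) == 0L) nodes <- empty_nodes()
  if (nrow(edges) == 0L) edges <- empty_edges()
  if (nrow(edges) > 0L) {
    if (is.null(edges$evidence)) edges$evidence <- NA_character_
    if (is.null(edges$weight)) edges$weight <- NA_real_
    edges$weight <- as.numeric(edges$weight)
  }
  g$nodes <- nodes[, names(empty_nodes()), drop = FALSE]
  g$edges <- edges[, names(empty_edges()), drop = FALSE]
  if (!is.null(obj$query))
    g$query <- as.data.frame(obj$query, stringsAsFactors = FALSE)
  kg_canonicalize(g)
}

#' Export a knowledge graph as GraphML
#'
#' Converts the graph to an igraph object with typed node attributes
#' (component, role, display name) and edge attributes (relation,
#' evidence, weight) and writes GraphML.
#'
#' @param graph a `kg_graph`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
kg_write_graphml <- function(graph, path) {
  ig <- kg_as_igraph(graph)
  igraph::write_graph(ig, path, format = "graphml")
  invisible(path)
}

#' Convert a knowledge graph to igraph
#'
#' @param graph a `kg_graph`.
#' @return an undirected-attribute-free conversion is deliberately not
#'   offered; returns a directed igraph with all node/edge attributes.
#' @export
kg_as_igraph <- function(graph) {
  g <- kg_canonicalize(graph)
  nodes <- g$nodes
  names(nodes)[names(nodes) == "node_id"] <- "name"
  edges <- g$edges
  edges$evidence[is.na(edges$evidence)] <- ""
  igraph::graph_from_data_frame(edges, directed = TRUE, vertices = nodes)
}

#' Protein-centric table of a knowledge graph
#'
#' One row per gene/protein node with its role and pipe-delimited lists of
#' related nodes per component (interacting proteins, diseases, pathways,
#' phenotypes, targeting drugs and compounds).
#'
#' @param graph a `kg_graph`.
#' @return a `data.frame`, one row per protein node.
#' @export
kg_protein_table <- function(graph) {
  g <- kg_canonicalize(graph)
  prot <- g$nodes[g$nodes$component == "gene/protein", , drop = FALSE]
  comp <- stats::setNames(g$nodes$component, g$nodes$node_id)
  e <- g$edges
  rel_of <- function(pid, other_comp) {
    hit <- c(e$to[e$from == pid & comp[e$to] == other_comp],
             e$from[e$to == pid & comp[e$from] == other_comp])
    paste(sort(unique(hit)), collapse = "|")
  }
  data.frame(
    protein_id = prot$node_id,
    gene_symbol = prot$display_name,
    role = prot$role,
    interacts_with = vapply(prot$node_id, rel_of, character(1), "gene/protein"),
    diseases = vapply(prot$node_id, rel_of, character(1), "disease"),
    pathways = vapply(prot$node_id, rel_of, character(1), "pathway"),
    phenotypes = vapply(prot$node_id, rel_of, character(1), "phenotype"),
    drugs = vapply(prot$node_id, rel_of, character(1), "drug"),
    compounds = vapply(prot$node_id, rel_of, character(1), "compound"),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Write the per-component query report
#'
#' One TSV with the ranked candidates of every component: enrichment score
#' E, significance S (reported for the top 100 candidates per component)
#' and whether the term was included in the graph.
#'
#' @param graph a built `kg_graph`.
#' @param path output TSV file.
#' @return `path`, invisibly.
#' @export
kg_write_report <- function(graph, path) {
  tabs <- graph$report
  if (length(tabs) == 0L) stop_kg("graph carries no report tables")
  all <- do.call(rbind, tabs)
  rownames(all) <- NULL
  utils::write.table(all, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
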