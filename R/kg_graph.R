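# The heterogeneous knowledge-graph container: typed nodes, typed
# evidence-labelled edges, relation vocabulary, canonical ordering.

NODE_ROLES <- c("query", "core_protein", "neighbour_protein", "enriched",
                "merged_drug")
EDGE_RELATIONS <- c("interacts with", "is related to", "targets",
                    "is involved in", "is associated with", "indicates",
                    "modulates", "is ortholog of")
EVIDENCE_LEVELS <- c("approved", "experimental", "predicted")

# Legal relations per (ordered) endpoint component pair. "is ortholog of"
# is vocabulary-supported for imported curated graphs; the automatic
# pipeline never emits it.
RELATION_VOCAB <- data.frame(
  from = c("gene/protein", "gene/protein", "drug", "compound",
           "gene/protein", "gene/protein", "drug", "disease", "disease",
           "gene/protein"),
  to = c("gene/protein", "disease", "gene/protein", "gene/protein",
         "pathway", "phenotype", "disease", "pathway", "phenotype",
         "gene/protein"),
  relation = c("interacts with", "is related to", "targets", "targets",
               "is involved in", "is associated with", "indicates",
               "modulates", "is associated with", "is ortholog of"),
  stringsAsFactors = FALSE
)

# Canonical relation for a component pair (error when illegal).
relation_for <- function(comp_from, comp_to) {
  hit <- RELATION_VOCAB$relation[RELATION_VOCAB$from == comp_from &
                                 RELATION_VOCAB$to == comp_to]
  hit <- setdiff(hit, "is ortholog of")
  if (length(hit) == 0L)
    stop_kg("no legal relation between components '%s' and '%s'",
            comp_from, comp_to)
  hit[1L]
}

relation_is_legal <- function(comp_from, comp_to, relation) {
  any(RELATION_VOCAB$from == comp_from & RELATION_VOCAB$to == comp_to &
      RELATION_VOCAB$relation == relation)
}

empty_nodes <- function() {
  data.frame(node_id = character(0), component = character(0),
             role = character(0), display_name = character(0),
             provenance = character(0), stringsAsFactors = FALSE)
}

empty_edges <- function() {
  data.frame(from = character(0), to = character(0),
             relation = character(0), evidence = character(0),
             weight = numeric(0), stringsAsFactors = FALSE)
}

new_kg_graph <- function(query = NULL, params = NULL) {
  structure(list(nodes = empty_nodes(), edges = empty_edges(),
                 query = query, params = params,
                 report = list(), layout = NULL),
            class = "kg_graph")
}

# Add nodes, ignoring ids already present (first placement wins, so a
# query node is never downgraded to an enriched one).
kg_add_nodes <- function(graph, nodes) {
  if (nrow(nodes) == 0L) return(graph)
  stopifnot(all(nodes$component %in% KG_COMPONENTS),
            all(nodes$role %in% NODE_ROLES))
  nodes <- nodes[!duplicated(nodes$node_id), , drop = FALSE]
  clash <- nodes$node_id %in% graph$nodes$node_id
  if (any(clash)) {
    prev <- graph$nodes$component[match(nodes$node_id[clash],
                                        graph$nodes$node_id)]
    if (any(prev != nodes$component[clash]))
      stop_kg("node id reused across components: %s",
              paste(nodes$node_id[clash][prev != nodes$component[clash]],
                    collapse = ", "))
  }
  graph$nodes <- rbind(graph$nodes, nodes[!clash, , drop = FALSE])
  graph
}

# Add edges after vocabulary validation; exact duplicates collapse.
# `evidence` must be present iff the relation is "targets".
kg_add_edges <- function(graph, edges) {
  if (nrow(edges) == 0L) return(graph)
  comp <- stats::setNames(graph$nodes$component, graph$nodes$node_id)
  if (!all(edges$from %in% names(comp)) || !all(edges$to %in% names(comp)))
    stop_kg("edge endpoint not in graph")
  cf <- comp[edges$from]; ct <- comp[edges$to]
  ok <- mapply(relation_is_legal, cf, ct, edges$relation)
  if (!all(ok))
    stop_kg("illegal relation '%s' between %s and %s",
            edges$relation[!ok][1L], cf[!ok][1L], ct[!ok][1L])
  ev_ok <- ifelse(edges$relation == "targets",
                  edges$evidence %in% EVIDENCE_LEVELS,
                  is.na(edges$evidence))
  if (!all(ev_ok))
    stop_kg("evidence must be present iff the relation is 'targets'")
  all_edges <- rbind(graph$edges, edges)
  key <- paste(all_edges$from, all_edges$to, all_edges$relation,
               all_edges$evidence, sep = "\r")
  graph$edges <- all_edges[!duplicated(key), , drop = FALSE]
  graph
}

kg_node_degree <- function(graph) {
  deg <- stats::setNames(integer(nrow(graph$nodes)), graph$nodes$node_id)
  tab <- table(c(graph$edges$from, graph$edges$to))
  deg[names(tab)] <- as.integer(tab)
  deg
}

# Remove degree-0 non-query nodes; query anchors always stay visible.
kg_prune <- function(graph) {
  deg <- kg_node_degree(graph)
  keep <- deg[graph$nodes$node_id] > 0L | graph$nodes$role == "query"
  graph$nodes <- graph$nodes[keep, , drop = FALSE]
  graph
}

# Deterministic serialization order: nodes by (component, id), edges by
# (relation, from, to, evidence).
kg_canonicalize <- function(graph) {
  comp_rank <- match(graph$nodes$component, KG_COMPONENTS)
  graph$nodes <- graph$nodes[order_radix(comp_rank, graph$nodes$node_id),
                             , drop = FALSE]
  e <- graph$edges
  graph$edges <- e[order_radix(e$relation, e$from, e$to, e$evidence),
                   , drop = FALSE]
  rownames(graph$nodes) <- rownames(graph$edges) <- NULL
  graph
}

# Protein node ids currently in the graph.
kg_graph_proteins <- function(graph) {
  graph$nodes$node_id[graph$nodes$component == "gene/protein"]
}

#' @export
print.kg_graph <- function(x, ...) {
  cat(sprintf("<kg_graph> %d node(s), %d edge(s)\n",
              nrow(x$nodes), nrow(x$edges)))
  if (nrow(x$nodes) > 0L) {
    tab <- table(x$nodes$component)
    cat("  nodes:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "),
        "\n")
  }
  if (nrow(x$edges) > 0L) {
    tab <- table(x$edges$relation)
    cat("  edges:", paste(sprintf("'%s'=%d", names(tab), tab), collapse = " "),
        "\n")
  }
  if (!is.null(x$query))
    cat("  query:", paste(sprintf("%s:%s", x$query$component, x$query$term_id),
                          collapse = ", "), "\n")
  invisible(x)
}
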