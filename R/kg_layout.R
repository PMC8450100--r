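# Concentric multi-layer layouts for heterogeneous graphs.

# Layer grouping. 7 layers keep every component (and the core/neighbour
# protein split) separate; 4 layers merge biologically similar components.
layer_of <- function(nodes, layers) {
  if (layers == 7L) {
    ifelse(nodes$component == "gene/protein",
           ifelse(nodes$role %in% c("neighbour_protein"), "neighbour proteins",
                  "core proteins"),
           c(disease = "diseases", pathway = "pathways",
             phenotype = "phenotypes", drug = "drugs",
             compound = "compounds")[nodes$component])
  } else {
    c(`gene/protein` = "proteins", pathway = "pathways",
      disease = "diseases+phenotypes", phenotype = "diseases+phenotypes",
      drug = "drugs+compounds", compound = "drugs+compounds")[nodes$component]
  }
}

LAYER_ORDER_7 <- c("core proteins", "neighbour proteins", "pathways",
                   "diseases", "phenotypes", "drugs", "compounds")
LAYER_ORDER_4 <- c("proteins", "pathways", "diseases+phenotypes",
                   "drugs+compounds")

#' Concentric circular layout coordinates
#'
#' Places each layer's nodes evenly spaced by angle on a circle, in the
#' deterministic order (component, then node id). The nested style assigns
#' strictly increasing radii per layer around one common centre; the
#' isolated style draws each layer as its own unit circle with disjoint,
#' horizontally offset centres. Empty layers are skipped.
#'
#' @param graph a non-empty `kg_graph`.
#' @param style `"nested"` (default) or `"isolated"`.
#' @param layers 7 (default) or 4.
#' @return a `data.frame` with columns `node_id`, `layer`, `x`, `y`,
#'   also stored on the returned graph by [build_knowledge_graph()] users
#'   via `graph$layout <- compute_layout(graph)`.
#' @export
compute_layout <- function(graph, style = c("nested", "isolated"),
                           layers = 7L) {
  style <- match.arg(style)
  stopifnot(inherits(graph, "kg_graph"), layers %in% c(4L, 7L))
  if (nrow(graph$nodes) == 0L) stop_kg("cannot lay out an empty graph")
  nodes <- kg_canonicalize(graph)$nodes
  lay <- layer_of(nodes, layers)
  order_tab <- if (layers == 7L) LAYER_ORDER_7 else LAYER_ORDER_4
  present <- order_tab[order_tab %in% lay]
  out <- data.frame(node_id = character(0), layer = character(0),
                    x = numeric(0), y = numeric(0), stringsAsFactors = FALSE)
  for (li in seq_along(present)) {
    ids <- nodes$node_id[lay == present[li]]  # canonical order already
    nl <- length(ids)
    theta <- 2 * pi * (seq_len(nl) - 1L) / nl
    if (style == "nested") {
      r <- li  # strictly increasing radius per layer
      cx <- 0; cy <- 0
    } else {
      r <- 1
      cx <- (li - 1L) * 2.5  # disjoint unit circles along a row
      cy <- 0
    }
    out <- rbind(out, data.frame(node_id = ids, layer = present[li],
                                 x = cx + r * cos(theta),
                                 y = cy + r * sin(theta),
                                 stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}
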