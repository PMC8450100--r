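# Diversity and stability analyses over collections of knowledge graphs:
# pairwise node identity, observed-vs-expected term frequency with
# Fisher's exact test, and graph censuses.

kg_node_keys <- function(graph) {
  paste(graph$nodes$component, graph$nodes$node_id, sep = "\r")
}

#' Pairwise node identity between two knowledge graphs
#'
#' Counts nodes shared by identifier and component, and expresses the
#' overlap as a percentage. The denominator convention is recorded in the
#' result because headline identity percentages cannot be compared across
#' conventions: `jaccard` (default) divides by the union, `min` by the
#' smaller graph, `mean` by the average size.
#'
#' @param a,b `kg_graph` objects sharing a node-id namespace.
#' @param mode denominator convention.
#' @return a one-row `data.frame`: `graph_a`, `graph_b`, `shared_nodes`,
#'   `identity_pct`, `mode`.
#' @export
node_identity <- function(a, b, mode = c("jaccard", "min", "mean")) {
  mode <- match.arg(mode)
  ka <- kg_node_keys(a); kb <- kg_node_keys(b)
  if (length(ka) == 0L && length(kb) == 0L)
    stop_kg("node identity undefined for two empty graphs")
  shared <- length(intersect(ka, kb))
  denom <- switch(mode,
                  jaccard = length(union(ka, kb)),
                  min = min(length(ka), length(kb)),
                  mean = (length(ka) + length(kb)) / 2)
  data.frame(graph_a = attr(a, "label") %||% NA_character_,
             graph_b = attr(b, "label") %||% NA_character_,
             shared_nodes = shared,
             identity_pct = 100 * shared / denom,
             mode = mode, stringsAsFactors = FALSE)
}

#' Pairwise node-identity matrix over a graph collection
#'
#' @param graphs a (preferably named) list of `kg_graph` objects.
#' @param mode denominator convention, see [node_identity()].
#' @return a symmetric numeric matrix of identity percentages (diagonal
#'   100).
#' @export
kg_identity_matrix <- function(graphs, mode = c("jaccard", "min", "mean")) {
  mode <- match.arg(mode)
  n <- length(graphs)
  keys <- lapply(graphs, kg_node_keys)
  out <- matrix(100, n, n,
                dimnames = list(names(graphs), names(graphs)))
  if (n < 2L) return(out)
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      shared <- length(intersect(keys[[i]], keys[[j]]))
      denom <- switch(mode,
                      jaccard = length(union(keys[[i]], keys[[j]])),
                      min = min(length(keys[[i]]), length(keys[[j]])),
                      mean = (length(keys[[i]]) + length(keys[[j]])) / 2)
      out[i, j] <- out[j, i] <- 100 * shared / denom
    }
  }
  out
}

#' Observed-vs-expected term frequency across a graph collection
#'
#' For each term, compares how often it appears across `G` graphs
#' (observed frequency `g/G`) with its connectivity-based expectation
#' `t * M_D / M_sum`, where `t` is the number of nodes each graph admits
#' from the term's component, `M_D` the term's protein association count
#' in the datastore, and `M_sum` the total number of protein-term
#' associations in that component. A hub term whose observed frequency
#' falls significantly below expectation is being suppressed by the
#' enrichment ranking.
#'
#' Significance per term is a one-tailed Fisher's exact test on the
#' pseudo-contingency table `[g, G - g; round(G * expected),
#' G - round(G * expected)]` (the test direction follows the deviation);
#' `method = "binomial"` instead tests `g ~ Binomial(G, expected)`.
#' Expected frequencies above 1 are clamped with a warning.
#'
#' @param graphs list of `kg_graph` objects.
#' @param ds the `kg_datastore` the graphs were built from.
#' @param terms a `data.frame` with columns `term_id` and `component`
#'   naming the terms to test.
#' @param t nodes per graph admitted from the same component (the k the
#'   graphs were built with).
#' @param alpha significance level for the reported direction (default
#'   0.05).
#' @param method `"fisher"` (default) or `"binomial"`.
#' @return a `data.frame` with one row per term: `term_id`, `component`,
#'   `g`, `G`, `observed_freq`, `expected_freq`, `p_value`, `direction`.
#' @export
term_frequency_analysis <- function(graphs, ds, terms, t,
                                    alpha = 0.05,
                                    method = c("fisher", "binomial")) {
  method <- match.arg(method)
  stopifnot(is.data.frame(terms), all(c("term_id", "component") %in%
                                        names(terms)))
  G <- length(graphs)
  if (G == 0L) stop_kg("no graphs to analyse")
  keys <- lapply(graphs, kg_node_keys)
  comp_for_index <- function(component)
    switch(component, drug = "drug", compound = "compound-experimental",
           component)
  out <- lapply(seq_len(nrow(terms)), function(i) {
    tid <- terms$term_id[i]; comp <- terms$component[i]
    key <- paste(comp, tid, sep = "\r")
    g <- sum(vapply(keys, function(k) key %in% k, logical(1)))
    idx <- ds$annotation_index[[comp_for_index(comp)]]
    M_D <- length(idx[[tid]] %||% character(0))
    M_sum <- sum(lengths(idx))
    expected <- if (M_sum > 0) t * M_D / M_sum else 0
    if (expected > 1) {
      warn_kg("expected frequency %.3f > 1 for term %s; clamped", expected,
              tid)
      expected <- 1
    }
    obs <- g / G
    e_cnt <- round(G * expected)
    p <- if (method == "fisher") {
      alt <- if (g <= e_cnt) "less" else "greater"
      stats::fisher.test(matrix(c(g, G - g, e_cnt, G - e_cnt), nrow = 2L),
                         alternative = alt)$p.value
    } else {
      alt <- if (obs <= expected) "less" else "greater"
      stats::binom.test(g, G, p = min(max(expected, 0), 1),
                        alternative = alt)$p.value
    }
    direction <- if (p < alpha) {
      if (obs < expected) "under" else "over"
    } else "none"
    data.frame(term_id = tid, component = comp, g = g, G = G,
               observed_freq = obs, expected_freq = expected,
               p_value = p, direction = direction, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Census of a knowledge graph
#'
#' Node counts per component and per role, edge counts per relation and
#' per evidence level, plus totals.
#'
#' @param graph a `kg_graph`.
#' @return a named list of count tables (plain named integer vectors).
#' @export
graph_statistics <- function(graph) {
  count_by <- function(x, levels) {
    tab <- table(factor(x, levels = levels))
    stats::setNames(as.integer(tab), names(tab))
  }
  ev <- graph$edges$evidence
  list(
    n_nodes = nrow(graph$nodes),
    n_edges = nrow(graph$edges),
    nodes_by_component = count_by(graph$nodes$component, KG_COMPONENTS),
    nodes_by_role = count_by(graph$nodes$role, NODE_ROLES),
    edges_by_relation = count_by(graph$edges$relation, EDGE_RELATIONS),
    edges_by_evidence = count_by(ev[!is.na(ev)], EVIDENCE_LEVELS)
  )
}
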