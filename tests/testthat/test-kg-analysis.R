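# Diversity/stability analyses: node identity, term frequency testing,
# graph censuses.

# Hand-built graphs with known node sets.
mini_graph <- function(ids, component = "gene/protein") {
  g <- kgforge:::new_kg_graph()
  if (length(ids) > 0L)
    g$nodes <- data.frame(node_id = ids, component = component,
                          role = "core_protein", display_name = ids,
                          provenance = "test", stringsAsFactors = FALSE)
  g
}

test_that("node identity implements the documented denominator conventions", {
  a <- mini_graph(sprintf("P%02d", 1:10))
  b <- mini_graph(sprintf("P%02d", 7:12))  # |a|=10, |b|=6, shared=4
  expect_equal(node_identity(a, a)$identity_pct, 100)
  expect_equal(node_identity(a, mini_graph("Z1"))$identity_pct, 0)
  expect_equal(node_identity(a, b, "jaccard")$identity_pct, 100 * 4 / 12)
  expect_equal(node_identity(a, b, "min")$identity_pct, 100 * 4 / 6)
  expect_equal(node_identity(a, b, "mean")$identity_pct, 100 * 4 / 8)
  # symmetry
  for (mode in c("jaccard", "mean"))
    expect_equal(node_identity(a, b, mode)$identity_pct,
                 node_identity(b, a, mode)$identity_pct)
  # nodes match on identifier AND component
  c_dis <- mini_graph(sprintf("P%02d", 1:10), component = "disease")
  expect_equal(node_identity(a, c_dis)$shared_nodes, 0L)
  expect_error(node_identity(mini_graph(character(0)),
                             mini_graph(character(0))), "empty")
})

test_that("identity matrix is symmetric with a 100 diagonal", {
  ds <- cached_synth_view()
  qs <- generate_query_set(ds, n_per_component = 1L, combinatory = 0L,
                           seed = 3L)
  graphs <- lapply(qs[1:4], function(q) build_knowledge_graph(q, ds))
  m <- kg_identity_matrix(graphs)
  expect_equal(m, t(m))
  expect_equal(unname(diag(m)), rep(100, 4))
  expect_true(all(m >= 0 & m <= 100))
})

test_that("frequency analysis recovers forced directions", {
  g_with <- mini_graph(c("P01", "T1"))
  g_with$nodes$component[2] <- "disease"
  g_without <- mini_graph("P01")
  ds <- cached_synth_view()

  # term present in every graph with expected 0.5 -> over
  graphs <- rep(list(g_with), 40)
  terms <- data.frame(term_id = "T1", component = "disease",
                      stringsAsFactors = FALSE)
  # fabricate M so that expected = t*M/M_sum = 0.5: use t chosen from the
  # datastore's disease index
  idx <- ds$annotation_index$disease
  M_sum <- sum(lengths(idx))
  some_term <- names(idx)[1]
  t_use <- 10
  res <- suppressWarnings(term_frequency_analysis(
    graphs, ds, data.frame(term_id = some_term, component = "disease"),
    t = t_use))
  # the synthetic term is absent from these fabricated graphs: direction
  # under whenever expected is materially positive
  expect_equal(res$g, 0L)
  expect_true(res$direction %in% c("under", "none"))

  # g equal to the expected count -> maximal p, no direction
  G <- 40L
  expected <- 0.5
  g_eq <- round(G * expected)
  g_term <- mini_graph(some_term, component = "disease")
  graphs_eq <- c(rep(list(g_term), g_eq), rep(list(g_without), G - g_eq))
  # choose t so the term's expected frequency is exactly 0.5
  t_half <- 0.5 * M_sum / lengths(idx)[[some_term]]
  res_eq <- suppressWarnings(term_frequency_analysis(
    graphs_eq, ds, data.frame(term_id = some_term, component = "disease"),
    t = t_half))
  # at the mode of the one-tailed test no direction is called
  expect_equal(res_eq$direction, "none")
  expect_gt(res_eq$p_value, 0.5)
  expect_equal(res_eq$observed_freq, res_eq$expected_freq)
})

test_that("under-direction p decreases as the observed count drops", {
  ds <- cached_synth_view()
  idx <- ds$annotation_index$disease
  some_term <- names(idx)[1]
  key_node <- mini_graph(some_term, component = "disease")
  absent <- mini_graph("P01")
  M_sum <- sum(lengths(idx))
  t_half <- 0.5 * M_sum / lengths(idx)[[some_term]]
  p_at_g <- function(g, G = 60L) {
    graphs <- c(rep(list(key_node), g), rep(list(absent), G - g))
    suppressWarnings(term_frequency_analysis(
      graphs, ds, data.frame(term_id = some_term, component = "disease"),
      t = t_half))$p_value
  }
  ps <- vapply(c(25L, 15L, 5L, 0L), p_at_g, numeric(1))
  expect_true(all(diff(ps) < 0))
  expect_true(all(ps >= 0 & ps <= 1))
})

test_that("frequency conservation: term g sums equal component node counts", {
  ds <- cached_synth_view()
  qs <- generate_query_set(ds, n_per_component = 2L, combinatory = 0L,
                           seed = 8L)
  graphs <- lapply(qs, function(q) build_knowledge_graph(q, ds))
  all_dis <- data.frame(
    term_id = names(ds$annotation_index$disease),
    component = "disease", stringsAsFactors = FALSE)
  res <- suppressWarnings(term_frequency_analysis(graphs, ds, all_dis,
                                                  t = 10))
  per_graph <- vapply(graphs, function(g)
    sum(g$nodes$component == "disease" &
        g$nodes$node_id %in% all_dis$term_id), 0L)
  expect_equal(sum(res$g), sum(per_graph))
})

test_that("graph census counts nodes and edges by type", {
  g <- mini_graph(c("P01", "P02"))
  g$nodes <- rbind(g$nodes, data.frame(
    node_id = "D1", component = "disease", role = "enriched",
    display_name = "D1", provenance = "test", stringsAsFactors = FALSE))
  g$edges <- data.frame(from = c("P01", "P01"), to = c("P02", "D1"),
                        relation = c("interacts with", "is related to"),
                        evidence = NA_character_, weight = c(0.9, NA),
                        stringsAsFactors = FALSE)
  st <- graph_statistics(g)
  expect_equal(st$n_nodes, 3L)
  expect_equal(st$n_edges, 2L)
  expect_equal(unname(st$nodes_by_component[["gene/protein"]]), 2L)
  expect_equal(unname(st$nodes_by_component[["disease"]]), 1L)
  expect_equal(unname(st$edges_by_relation[["interacts with"]]), 1L)
  expect_equal(sum(st$edges_by_evidence), 0L)
  # empty-but-query graph: all zeros except the query anchor
  q <- mini_graph("P01"); q$nodes$role <- "query"
  stq <- graph_statistics(q)
  expect_equal(stq$n_edges, 0L)
  expect_equal(unname(stq$nodes_by_role[["query"]]), 1L)
})
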