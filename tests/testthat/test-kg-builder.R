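# The construction workflow: core collection, neighbour expansion,
# enriched terms, ligands, evidence labelling, cross edges, invariants.

tiny_view <- function() {
  ds <- load_datastore(write_tiny_datastore(), strict = TRUE)
  filter_proteins_by_taxon(ds, 9606L, reviewed_only = TRUE)
}

test_that("query terms resolve by id, exact name, then case-insensitive name", {
  ds <- tiny_view()
  q <- resolve_query <- collect_core_proteins(query_spec(disease = "D1"), ds)
  expect_equal(as.character(q), c("P01", "P02", "P03", "P06"))
  by_name <- collect_core_proteins(query_spec(disease = "alpha syndrome"), ds)
  expect_equal(as.character(by_name), as.character(q))
  by_ci <- collect_core_proteins(query_spec(disease = "ALPHA Syndrome"), ds)
  expect_equal(as.character(by_ci), as.character(q))
  expect_error(collect_core_proteins(query_spec(disease = "no such"), ds),
               "not resolvable")
})

test_that("core collection unions per-term contributions", {
  ds <- tiny_view()
  # gene + disease query: {P07} union proteins(D2) = {P04, P05, P07}
  core <- collect_core_proteins(query_spec(gene = "P07", disease = "D2"), ds)
  expect_equal(as.character(core), c("P04", "P05", "P07"))
  prov <- attr(core, "provenance")
  expect_equal(prov$P07, "P07")
  expect_equal(prov$D2, c("P04", "P05"))
  # drug with a non-human target: only the human target survives
  core <- collect_core_proteins(query_spec(drug = "DRB"), ds)
  expect_equal(as.character(core), "P04")  # P41 is mouse
  # compound query: experimental + predicted targets
  core <- collect_core_proteins(query_spec(compound = "CB"), ds)
  expect_equal(as.character(core), c("P01", "P02", "P05"))
})

test_that("neighbour expansion scores candidates like the enrichment oracle", {
  ds <- tiny_view()
  core <- c("P01", "P02")
  nb <- expand_neighbours(core, ds, k = 2L)
  ranked <- attr(nb, "ranking")
  # brute force: candidates are first neighbours not in the core
  idx <- ds$ppi_index
  cand <- sort(setdiff(unique(unlist(idx[core])), core))
  n <- length(intersect(core, names(idx)))
  N <- length(idx)
  brute <- data.frame(
    term_id = cand,
    m = vapply(idx[cand], function(p) length(intersect(p, core)), 0L),
    M = lengths(idx[cand]))
  brute$E <- (brute$m^2 / n) / (brute$M / N)
  brute <- brute[order(-brute$E, brute$term_id), ]
  expect_equal(ranked$term_id, brute$term_id)
  expect_equal(ranked$E, brute$E)
  expect_equal(as.character(nb), brute$term_id[1:2])
  # low-degree candidate beats a hub at equal m
  expect_true(ranked$M[1] <= ranked$M[nrow(ranked)] ||
              ranked$m[1] > ranked$m[nrow(ranked)])
  # no PPIs -> empty
  expect_length(expand_neighbours("P50", ds, 5L), 0L)
})

test_that("a default build satisfies the structural invariants", {
  ds <- cached_synth_view()
  g <- build_knowledge_graph(query_spec(gene = "P0003"), ds)
  nodes <- g$nodes; edges <- g$edges

  # k-cap per component (the query's own component excluded from the cap)
  for (comp in c("disease", "pathway", "phenotype", "drug", "compound")) {
    n_enriched <- sum(nodes$component == comp & nodes$role != "query")
    expect_lte(n_enriched, 10L)
  }
  expect_lte(sum(nodes$role == "neighbour_protein"), 10L)

  # no dangling edges, no duplicate nodes
  expect_true(all(c(edges$from, edges$to) %in% nodes$node_id))
  expect_false(any(duplicated(nodes$node_id)))

  # relation vocabulary closure
  comp <- setNames(nodes$component, nodes$node_id)
  legal <- mapply(kgforge:::relation_is_legal, comp[edges$from],
                  comp[edges$to], edges$relation)
  expect_true(all(legal))

  # evidence present iff relation is "targets"
  expect_true(all(is.na(edges$evidence[edges$relation != "targets"])))
  expect_true(all(edges$evidence[edges$relation == "targets"] %in%
                    c("approved", "experimental", "predicted")))

  # at most one targets edge per (ligand, protein) pair
  te <- edges[edges$relation == "targets", ]
  expect_false(any(duplicated(paste(te$from, te$to))))

  # no degree-0 non-query nodes survive pruning
  deg <- table(c(edges$from, edges$to))
  isolated <- setdiff(nodes$node_id, names(deg))
  expect_true(all(nodes$role[nodes$node_id %in% isolated] == "query"))
})

test_that("repeated builds serialize byte-identically", {
  ds <- cached_synth_view()
  q <- query_spec(disease = "DIS0012")
  f1 <- tempfile(); f2 <- tempfile()
  kg_write_json(build_knowledge_graph(q, ds), f1)
  kg_write_json(build_knowledge_graph(q, ds), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("enriched term addition honours k and matches brute-force top-k", {
  ds <- cached_synth_view()
  g <- build_knowledge_graph(query_spec(gene = "P0003"), ds)
  gp <- g$nodes$node_id[g$nodes$component == "gene/protein"]
  for (comp in c("disease", "pathway")) {
    idx <- build_annotation_index(ds, comp)
    ranked <- rank_component_terms(gp, idx)
    placed <- g$nodes$node_id[g$nodes$component == comp &
                              g$nodes$role == "enriched"]
    expect_setequal(placed, head(ranked$term_id, 10L))
  }
  # report tables carry the ranking with an inclusion flag
  expect_true(all(c("disease", "pathway", "phenotype", "drug") %in%
                    names(g$report)))
  rep_d <- g$report$disease
  expect_equal(sum(rep_d$included), 10L)
  expect_lte(nrow(rep_d), 100L)
})

test_that("a cross-referenced compound merges into its drug node", {
  ds <- tiny_view()
  g <- build_knowledge_graph(query_spec(gene = "P01"), ds)
  # DRA (targets P01, P02; xref CA) is enriched; CA ranks in the compound
  # pool, so it must merge: no CA compound node, DRA becomes merged_drug
  expect_false("CA" %in% g$nodes$node_id)
  dra <- g$nodes[g$nodes$node_id == "DRA", ]
  expect_equal(dra$component, "drug")
  expect_equal(dra$role, "merged_drug")
  # evidence priority: DRA-P01 pair has approved AND experimental
  # provenance; a single approved edge must remain
  e <- g$edges[g$edges$from == "DRA" & g$edges$to == "P01", ]
  expect_equal(nrow(e), 1L)
  expect_equal(e$evidence, "approved")
})

test_that("evidence reconciliation keeps the highest priority and is idempotent", {
  ds <- tiny_view()
  g <- build_knowledge_graph(query_spec(gene = "P01"), ds)
  g2 <- reconcile_edge_labels(g, ds, g$params)
  expect_identical(kgforge:::kg_canonicalize(g2)$edges,
                   kgforge:::kg_canonicalize(g)$edges)
  # a pair with only predicted evidence stays predicted
  te <- g$edges[g$edges$relation == "targets", ]
  pred_pairs <- ds$predicted_dtis
  only_pred <- te[te$from == "CD", ]
  if (nrow(only_pred) > 0L)
    expect_true(all(only_pred$evidence == "predicted"))
})

test_that("evidence toggles suppress their edge classes", {
  ds <- cached_synth_view()
  q <- query_spec(gene = "P0003")
  g_noexp <- build_knowledge_graph(q, ds,
                                   build_params(include_experimental = FALSE))
  expect_false(any(g_noexp$edges$evidence %in% "experimental"))
  g_nopred <- build_knowledge_graph(q, ds,
                                    build_params(include_predictions = FALSE))
  expect_false(any(g_nopred$edges$evidence %in% "predicted"))
})

test_that("cross-component edges match a brute-force join on the tables", {
  ds <- cached_synth_view()
  g <- build_knowledge_graph(query_spec(disease = "DIS0005"), ds)
  nodes <- g$nodes
  drugs <- nodes$node_id[nodes$component == "drug"]
  diseases <- nodes$node_id[nodes$component == "disease"]
  pathways <- nodes$node_id[nodes$component == "pathway"]
  # brute force drug -> disease indications
  want <- do.call(rbind, lapply(drugs, function(d) {
    ind <- ds$drugs$indication_disease_ids[[match(d, ds$drugs$drug_id)]]
    hit <- intersect(ind, diseases)
    if (length(hit) == 0L) return(NULL)
    data.frame(from = d, to = hit, stringsAsFactors = FALSE)
  }))
  got <- g$edges[g$edges$relation == "indicates", c("from", "to")]
  rownames(got) <- NULL
  if (is.null(want)) {
    expect_equal(nrow(got), 0L)
  } else {
    want <- want[order(want$from, want$to), ]
    rownames(want) <- NULL
    expect_equal(got[order(got$from, got$to), ], want,
                 ignore_attr = TRUE)
  }
  # disease -> pathway edges only between placed nodes
  mod <- g$edges[g$edges$relation == "modulates", ]
  expect_true(all(mod$from %in% diseases) && all(mod$to %in% pathways))
})

test_that("layout places layers on circles with even angular spacing", {
  ds <- cached_synth_view()
  g <- build_knowledge_graph(query_spec(gene = "P0003"), ds)
  lay <- compute_layout(g, "nested", 7L)
  expect_setequal(lay$node_id, g$nodes$node_id)
  radii <- sort(unique(round(sqrt(lay$x^2 + lay$y^2), 9)))
  layers_present <- length(unique(lay$layer))
  expect_equal(length(radii), layers_present)  # distinct radius per layer
  # even angular gaps within a populated layer
  one <- lay[lay$layer == "pathways", ]
  ang <- sort(atan2(one$y, one$x) %% (2 * pi))
  gaps <- diff(c(ang, ang[1] + 2 * pi))
  expect_equal(gaps, rep(2 * pi / nrow(one), nrow(one)), tolerance = 1e-9)
  # isolated layout: disjoint unit circles
  iso <- compute_layout(g, "isolated", 4L)
  centres <- unique(round(tapply(iso$x, iso$layer, function(v) mean(range(v))),
                          6))
  expect_equal(length(centres), length(unique(iso$layer)))
  # a singleton layer sits at angle 0 on its circle
  g1 <- g
  lay1 <- compute_layout(g1, "nested", 7L)
  counts <- table(lay1$layer)
  if (any(counts == 1L)) {
    solo <- lay1[lay1$layer == names(counts)[counts == 1L][1L], ]
    expect_equal(atan2(solo$y, solo$x), 0)
  }
})

test_that("export round trip preserves the census and protein table", {
  ds <- cached_synth_view()
  g <- build_knowledge_graph(query_spec(gene = "P0003"), ds)
  f <- tempfile(fileext = ".json")
  kg_write_json(g, f)
  g2 <- kg_read_json(f)
  expect_equal(graph_statistics(g2), graph_statistics(g))
  pt <- kg_protein_table(g)
  expect_setequal(pt$protein_id,
                  g$nodes$node_id[g$nodes$component == "gene/protein"])
  # GraphML export is well-formed XML with all nodes
  gm <- tempfile(fileext = ".graphml")
  kg_write_graphml(g, gm)
  doc <- xml2::read_xml(gm)
  expect_equal(length(xml2::xml_find_all(doc, ".//d1:node",
                                         xml2::xml_ns(doc))),
               nrow(g$nodes))
  # query report writes one row per reported candidate
  rp <- tempfile(fileext = ".tsv")
  kg_write_report(g, rp)
  tab <- read.delim(rp)
  expect_equal(nrow(tab), sum(vapply(g$report, nrow, 0L)))
})
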