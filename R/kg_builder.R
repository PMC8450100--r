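# Builder: orchestrates the construction workflow around gene/protein
# entries: query resolution, core-protein collection, PPI neighbour
# expansion, component-wise enriched term addition, ligand incorporation,
# evidence-priority edge labelling, cross-component edges and pruning.

#' Query specification
#'
#' A query is one or more (component, identifier-or-name) terms. Accepts
#' named arguments (`disease = "DIS0001"`, `gene = "P0007"`) and/or
#' `"component:identifier"` strings. Component aliases `gene` and
#' `protein` map to `gene/protein`.
#'
#' @param ... query terms as named arguments or `"component:id"` strings.
#' @return a `kg_query` data frame with columns `component` and `key`.
#' @examples
#' query_spec(gene = "P0001", disease = "DIS0003")
#' query_spec("drug:DRG0001")
#' @export
query_spec <- function(...) {
  args <- list(...)
  comps <- character(0); keys <- character(0)
  alias <- c(gene = "gene/protein", protein = "gene/protein",
             `gene/protein` = "gene/protein", disease = "disease",
             pathway = "pathway", phenotype = "phenotype", drug = "drug",
             compound = "compound")
  lookup <- function(name) {
    key <- tolower(name)
    if (!key %in% names(alias)) stop_kg("unknown component '%s'", name)
    alias[[key]]
  }
  nm <- names(args) %||% rep("", length(args))
  for (i in seq_along(args)) {
    v <- as.character(args[[i]])
    if (nzchar(nm[i])) {
      comp <- lookup(nm[i])
      comps <- c(comps, rep(comp, length(v))); keys <- c(keys, v)
    } else {
      for (s in v) {
        parts <- regmatches(s, regexpr(":", s, fixed = TRUE), invert = TRUE)[[1]]
        if (length(parts) != 2L)
          stop_kg("query string must be 'component:identifier': %s", s)
        comps <- c(comps, lookup(parts[1L])); keys <- c(keys, parts[2L])
      }
    }
  }
  if (length(keys) == 0L) stop_kg("query must contain at least one term")
  structure(data.frame(component = comps, key = keys,
                       stringsAsFactors = FALSE),
            class = c("kg_query", "data.frame"))
}

#' Build parameters
#'
#' All tunables of the construction workflow, with the web-service
#' defaults: 10 nodes per biological component, human proteins only
#' (taxon 9606), reviewed entries only, both experimental bioactivities and
#' in silico DTI predictions included, compound pool bounds 1000-2500 with
#' the pChEMBL cutoff scan starting at 8 (floor 5, step 0.5), and
#' fingerprint clustering at Tanimoto 0.5.
#'
#' `ligand_min_E` / `ligand_max_S` optionally impose an absolute
#' enrichment-score floor and significance ceiling on drug/compound
#' candidates (both off by default).
#'
#' @param k nodes per component: a single number or a named vector keyed by
#'   component (`gene/protein` caps PPI neighbours).
#' @param taxa taxon filter for proteins (default 9606).
#' @param reviewed_only exclude unreviewed protein entries (default
#'   `TRUE`).
#' @param allow_unreviewed accessions exempt from `reviewed_only`.
#' @param include_experimental,include_predictions evidence toggles.
#' @param pool_lower,pool_upper,pool_start_cutoff,pool_floor,pool_step,pool_max_iter
#'   compound-pool search controls (see [assemble_compound_pool()]).
#' @param cluster_threshold,cluster_method compound clustering controls
#'   (see [cluster_compounds()]).
#' @param hpo_thinning reject phenotype candidates in a close parent-child
#'   relation with an already selected term (default `FALSE`).
#' @param ligand_min_E,ligand_max_S optional absolute thresholds on ligand
#'   candidates (`NULL` = off).
#' @param rng_seed recorded for provenance; the build itself is
#'   deterministic and draws no random numbers.
#' @return a `kg_build_params` list.
#' @export
build_params <- function(k = 10L, taxa = 9606L, reviewed_only = TRUE,
                         allow_unreviewed = character(0),
                         include_experimental = TRUE,
                         include_predictions = TRUE,
                         pool_lower = 1000L, pool_upper = 2500L,
                         pool_start_cutoff = 8, pool_floor = 5,
                         pool_step = 0.5, pool_max_iter = 20L,
                         cluster_threshold = 0.5,
                         cluster_method = c("leader", "single_linkage"),
                         hpo_thinning = FALSE,
                         ligand_min_E = NULL, ligand_max_S = NULL,
                         rng_seed = 1L) {
  if (is.null(names(k))) k <- stats::setNames(rep(as.integer(k),
                                                  length(KG_COMPONENTS)),
                                              KG_COMPONENTS)
  missing_k <- setdiff(KG_COMPONENTS, names(k))
  k <- c(k, stats::setNames(rep(10L, length(missing_k)), missing_k))
  stopifnot(all(k >= 0))
  structure(list(k = k, taxa = as.integer(taxa),
                 reviewed_only = reviewed_only,
                 allow_unreviewed = allow_unreviewed,
                 include_experimental = include_experimental,
                 include_predictions = include_predictions,
                 pool_lower = pool_lower, pool_upper = pool_upper,
                 pool_start_cutoff = pool_start_cutoff,
                 pool_floor = pool_floor, pool_step = pool_step,
                 pool_max_iter = pool_max_iter,
                 cluster_threshold = cluster_threshold,
                 cluster_method = match.arg(cluster_method),
                 hpo_thinning = hpo_thinning,
                 ligand_min_E = ligand_min_E, ligand_max_S = ligand_max_S,
                 rng_seed = as.integer(rng_seed)),
            class = "kg_build_params")
}

# Resolve one query term against the datastore: exact identifier first,
# then exact name, then case-insensitive name. Ambiguity is an error
# listing the candidates.
resolve_term <- function(ds, component, key) {
  tab <- switch(component,
    "gene/protein" = data.frame(id = ds$proteins$protein_id,
                                name = ds$proteins$gene_symbol,
                                stringsAsFactors = FALSE),
    "drug" = data.frame(id = ds$drugs$drug_id, name = ds$drugs$name,
                        stringsAsFactors = FALSE),
    "compound" = data.frame(id = ds$compounds$compound_id,
                            name = ds$compounds$name,
                            stringsAsFactors = FALSE),
    {
      sel <- ds$terms$component == component
      data.frame(id = ds$terms$term_id[sel], name = ds$terms$name[sel],
                 stringsAsFactors = FALSE)
    })
  if (key %in% tab$id) {
    i <- match(key, tab$id)
  } else {
    hits <- which(tab$name == key)
    if (length(hits) == 0L) hits <- which(tolower(tab$name) == tolower(key))
    if (length(hits) == 0L)
      stop_kg("query term not resolvable: %s '%s'", component, key)
    if (length(hits) > 1L)
      stop_kg("ambiguous query name '%s' (%s); candidates: %s", key,
              component, paste(tab$id[hits], collapse = ", "))
    i <- hits
  }
  list(term_id = tab$id[i], display_name = tab$name[i])
}

resolve_query <- function(ds, query) {
  stopifnot(inherits(query, "kg_query"))
  res <- lapply(seq_len(nrow(query)), function(i)
    resolve_term(ds, query$component[i], query$key[i]))
  data.frame(component = query$component,
             key = query$key,
             term_id = vapply(res, `[[`, character(1), "term_id"),
             display_name = vapply(res, `[[`, character(1), "display_name"),
             stringsAsFactors = FALSE)
}

# Proteins directly associated with one resolved query term.
term_associated_proteins <- function(ds, component, term_id) {
  switch(component,
    "gene/protein" = intersect(term_id, ds$proteins$protein_id),
    "disease" = ,
    "pathway" = ,
    "phenotype" = ds$annotation_index[[component]][[term_id]] %||% character(0),
    "drug" = ds$annotation_index[["drug"]][[term_id]] %||% character(0),
    "compound" = sort(unique(c(
      ds$annotation_index[["compound-experimental"]][[term_id]] %||% character(0),
      ds$annotation_index[["compound-predicted"]][[term_id]] %||% character(0)))),
    stop_kg("unknown component '%s'", component))
}

#' Collect the core proteins of a query
#'
#' For each query term, gathers its directly associated gene/protein
#' entries (disease/phenotype annotation, pathway membership, drug or
#' compound targets; a gene/protein term contributes itself), then takes
#' the union across terms -- combinatory queries continue with the union
#' as the source. The datastore view is expected to be taxon/review
#' filtered already.
#'
#' @param query a `kg_query` (see [query_spec()]).
#' @param ds a filtered `kg_datastore` view.
#' @return character vector of core accessions, with a `provenance`
#'   attribute (per-term protein lists) and a `resolved` attribute (the
#'   resolved query table).
#' @export
collect_core_proteins <- function(query, ds) {
  rq <- resolve_query(ds, query)
  prov <- lapply(seq_len(nrow(rq)), function(i) {
    p <- term_associated_proteins(ds, rq$component[i], rq$term_id[i])
    if (length(p) == 0L)
      warn_kg("query term %s '%s' has no associated proteins in the view",
              rq$component[i], rq$term_id[i])
    sort(p)
  })
  names(prov) <- rq$term_id
  core <- sort(unique(unlist(prov, use.names = FALSE)))
  attr(core, "provenance") <- prov
  attr(core, "resolved") <- rq
  core
}

#' Rank and select PPI first-neighbours of a core protein set
#'
#' Candidates are first neighbours of the core that are not core
#' themselves. Each candidate is scored with the enrichment score, treating
#' its PPI partner list as its association set: m = core partners of the
#' candidate, n = core proteins with at least one PPI, M = the candidate's
#' total partner count, N = proteins with at least one PPI. The top-k
#' candidates (deterministic tie-breaks) are returned.
#'
#' @param core character vector of core accessions.
#' @param ds a filtered `kg_datastore` view.
#' @param k number of neighbours to keep.
#' @return character vector of neighbour accessions in rank order, with
#'   the full ranking in attribute `ranking`.
#' @export
expand_neighbours <- function(core, ds, k = 10L) {
  idx <- ds$ppi_index
  N <- unname(ds$component_totals[["ppi"]])
  cand <- sort(setdiff(unique(unlist(idx[intersect(core, names(idx))],
                                     use.names = FALSE)), core))
  empty <- character(0)
  attr(empty, "ranking") <- NULL
  if (length(cand) == 0L || k <= 0L) return(empty)
  n <- length(intersect(core, names(idx)))
  m <- vapply(idx[cand], function(p) length(intersect(p, core)), 0L)
  M <- lengths(idx[cand])
  ranked <- data.frame(term_id = cand, m = unname(m), n = n, M = unname(M),
                       N = N, E = unname(enrichment_score(m, n, M, N)),
                       S = unname(enrichment_pvalue(m, n, M, N)),
                       stringsAsFactors = FALSE)
  ranked <- ranked[order_radix(-ranked$E, ranked$S, -ranked$m, ranked$term_id),
                   , drop = FALSE]
  rownames(ranked) <- NULL
  class(ranked) <- c("kg_enrichment", "data.frame")
  out <- utils::head(ranked$term_id, k)
  attr(out, "ranking") <- ranked
  out
}

# Association edges between a term node and the graph's proteins.
term_protein_edges <- function(graph, ds, component, term_id) {
  gp <- kg_graph_proteins(graph)
  assoc <- intersect(term_associated_proteins(ds, component, term_id), gp)
  if (length(assoc) == 0L) return(empty_edges())
  if (component %in% c("disease", "pathway", "phenotype")) {
    # canonical direction: protein -> term
    data.frame(from = assoc, to = term_id,
               relation = relation_for("gene/protein", component),
               evidence = NA_character_, weight = NA_real_,
               stringsAsFactors = FALSE)
  } else {
    stop_kg("term_protein_edges only handles ontology components")
  }
}

#' Add the top-k enriched terms of one component to a graph
#'
#' Ranks all terms of the component against the graph's current protein
#' set (core plus neighbours, equally weighted), excludes terms that are
#' themselves query terms, keeps the top k (with optional ontology
#' parent-child thinning for phenotypes), adds them as nodes and connects
#' each to its associated graph proteins. The full ranking (with
#' significance values for the top 100) is stored in the graph's report.
#'
#' @param graph a `kg_graph` whose protein set is finalized.
#' @param component one of `disease`, `pathway`, `phenotype`.
#' @param ds a filtered `kg_datastore` view.
#' @param k number of terms to add.
#' @return the extended `kg_graph`.
#' @export
add_enriched_terms <- function(graph, component, ds,
                               k = graph$params$k[[component]] %||% 10L) {
  stopifnot(component %in% TERM_COMPONENTS)
  idx <- build_annotation_index(ds, component)
  query_ids <- if (!is.null(graph$query))
    graph$query$term_id[graph$query$component == component] else character(0)
  ranked <- rank_component_terms(kg_graph_proteins(graph), idx,
                                 exclusions = query_ids)
  admit <- NULL
  if (component == "phenotype" && isTRUE(graph$params$hpo_thinning))
    admit <- hpo_thinning_predicate(ds$terms)
  chosen <- select_top_k(ranked, k, admit)
  graph$report[[component]] <- report_table(ds, component, ranked,
                                            chosen$term_id)
  if (nrow(chosen) == 0L) return(graph)
  nm <- ds$terms$name[match(chosen$term_id, ds$terms$term_id)]
  graph <- kg_add_nodes(graph, data.frame(
    node_id = chosen$term_id, component = component, role = "enriched",
    display_name = nm, provenance = paste0("enrichment:", component),
    stringsAsFactors = FALSE))
  for (tid in chosen$term_id)
    graph <- kg_add_edges(graph, term_protein_edges(graph, ds, component, tid))
  graph
}

# Query-report table: top-100 ranked terms with an included flag.
report_table <- function(ds, component, ranked, included_ids) {
  top <- utils::head(ranked, 100L)
  nm <- switch(component,
    "drug" = ds$drugs$name[match(top$term_id, ds$drugs$drug_id)],
    "compound" = ds$compounds$name[match(top$term_id, ds$compounds$compound_id)],
    "gene/protein" = ds$proteins$gene_symbol[match(top$term_id,
                                                   ds$proteins$protein_id)],
    ds$terms$name[match(top$term_id, ds$terms$term_id)])
  data.frame(component = rep(component, nrow(top)), term_id = top$term_id,
             name = ifelse(is.na(nm), top$term_id, nm), m = top$m, M = top$M,
             E = top$E, S = top$S,
             included = top$term_id %in% included_ids,
             stringsAsFactors = FALSE)
}

# Optional absolute thresholds on ligand rankings (off by default).
apply_ligand_thresholds <- function(ranked, params) {
  if (!is.null(params$ligand_min_E))
    ranked <- ranked[ranked$E > params$ligand_min_E, , drop = FALSE]
  if (!is.null(params$ligand_max_S))
    ranked <- ranked[ranked$S < params$ligand_max_S, , drop = FALSE]
  ranked
}

# Fingerprints (named list) for a set of compound ids; ids without a
# usable fingerprint are reported in attr "missing".
compound_fingerprints <- function(ds, ids) {
  i <- match(ids, ds$compounds$compound_id)
  fps <- ds$compounds$fingerprint[i]
  names(fps) <- ids
  ok <- !is.na(i) & lengths(fps) > 0L
  out <- fps[ok]
  attr(out, "missing") <- ids[!ok]
  out
}

# Cluster a candidate set together with compounds already present in the
# graph (query compounds, xrefs of placed drugs), so the cluster-aware
# discard can see them. Ids without fingerprints become singleton clusters.
cluster_for_selection <- function(ds, candidate_ids, present_ids, params) {
  all_ids <- unique(c(candidate_ids, present_ids))
  fps <- compound_fingerprints(ds, all_ids)
  cl <- cluster_compounds(fps, threshold = params$cluster_threshold,
                          method = params$cluster_method)
  missing <- attr(fps, "missing")
  if (length(missing) > 0L) {
    extra <- stats::setNames(seq_along(missing) + length(cl$representatives),
                             missing)
    cl$assignment <- c(cl$assignment, extra)
    cl$representatives <- c(cl$representatives, missing)
  }
  cl
}

# Compound ids "present" in the graph from a clustering point of view:
# compound nodes only. A drug node's ChEMBL cross-reference is
# deliberately not counted here, so the top-ranked cross-referenced
# compound can still be selected and merged into its drug node; its
# cluster is claimed at selection time like any other.
graph_present_compounds <- function(graph, ds) {
  graph$nodes$node_id[graph$nodes$component == "compound"]
}

#' Incorporate drugs, bioactive compounds and predicted DTIs
#'
#' Three passes over the finalized protein set:
#' (a) drugs are ranked by enrichment on their target sets and the top k
#' added with `evidence = "approved"` target edges;
#' (b) when `include_experimental`, the experimental compound pool is
#' assembled through the iterative pChEMBL cutoff, ranked by enrichment,
#' cluster-diversified and added with `evidence = "experimental"` edges
#' (edge weight: best pChEMBL per pair);
#' (c) when `include_predictions`, predicted DTIs go through the same
#' enrichment plus cluster-diversity selection with
#' `evidence = "predicted"` edges (edge weight: prediction score).
#'
#' A selected compound that is the ChEMBL-side cross-reference of a drug
#' node already in the graph is merged into that drug node (the node keeps
#' the drug id and becomes role `merged_drug`); its edges attach to the
#' drug node.
#'
#' @param graph a `kg_graph` with finalized proteins.
#' @param ds a filtered `kg_datastore` view.
#' @param params a `kg_build_params`.
#' @return the extended `kg_graph`.
#' @export
incorporate_ligands <- function(graph, ds, params = graph$params) {
  gp <- kg_graph_proteins(graph)
  query_ids <- if (!is.null(graph$query)) graph$query$term_id else character(0)

  ## (a) approved drugs -------------------------------------------------
  idx <- build_annotation_index(ds, "drug")
  ranked <- rank_component_terms(gp, idx, exclusions = query_ids)
  ranked <- apply_ligand_thresholds(ranked, params)
  chosen <- select_top_k(ranked, params$k[["drug"]])
  graph$report[["drug"]] <- report_table(ds, "drug", ranked, chosen$term_id)
  if (nrow(chosen) > 0L) {
    nm <- ds$drugs$name[match(chosen$term_id, ds$drugs$drug_id)]
    graph <- kg_add_nodes(graph, data.frame(
      node_id = chosen$term_id, component = "drug", role = "enriched",
      display_name = nm, provenance = "enrichment:drug",
      stringsAsFactors = FALSE))
    for (did in chosen$term_id) {
      tg <- intersect(idx[[did]], gp)
      if (length(tg) > 0L)
        graph <- kg_add_edges(graph, data.frame(
          from = did, to = tg, relation = "targets", evidence = "approved",
          weight = NA_real_, stringsAsFactors = FALSE))
    }
  }

  ## (b) experimental bioactive compounds -------------------------------
  if (isTRUE(params$include_experimental)) {
    pool <- assemble_compound_pool(ds, gp,
                                   lower = params$pool_lower,
                                   upper = params$pool_upper,
                                   start_cutoff = params$pool_start_cutoff,
                                   floor = params$pool_floor,
                                   step = params$pool_step,
                                   max_iter = params$pool_max_iter,
                                   taxa = NULL)
    graph$pool <- pool[c("final_cutoff", "iterations", "floor_relaxed",
                         "max_iter_hit")]
    graph$pool$n_compounds <- length(pool$distinct_compounds)
    # association sets at the final cutoff over ALL view targets (M), not
    # just graph proteins (m)
    full <- filter_bioactivities(ds$bioactivities, taxa = NULL,
                                 pchembl_min = pool$final_cutoff)
    idx_exp <- invert_relation(full$target_protein_id, full$compound_id)
    N_exp <- length(unique(full$target_protein_id))
    cand_idx <- idx_exp[intersect(names(idx_exp), pool$distinct_compounds)]
    attr(cand_idx, "total") <- N_exp
    ranked <- rank_component_terms(gp, cand_idx,
                                   exclusions = c(query_ids,
                                                  graph$nodes$node_id))
    ranked <- apply_ligand_thresholds(ranked, params)
    present <- graph_present_compounds(graph, ds)
    if (nrow(ranked) > 0L) {
      cl <- cluster_for_selection(ds, ranked$term_id, present, params)
      taken <- unname(cl$assignment[intersect(present, names(cl$assignment))])
      chosen <- select_diverse_compounds(ranked, cl, params$k[["compound"]],
                                         already_present_clusters = taken)
    } else chosen <- ranked
    graph$report[["compound"]] <- report_table(ds, "compound", ranked,
                                               chosen$term_id)
    xref_drug <- stats::setNames(ds$drugs$drug_id, ds$drugs$compound_xref)
    for (cid in chosen$term_id) {
      drug_of <- if (cid %in% names(xref_drug)) xref_drug[[cid]] else NA_character_
      merged <- !is.na(drug_of) && drug_of %in% graph$nodes$node_id
      node <- if (merged) drug_of else cid
      if (merged) {
        graph$nodes$role[graph$nodes$node_id == drug_of] <- "merged_drug"
      } else {
        nm <- ds$compounds$name[match(cid, ds$compounds$compound_id)]
        graph <- kg_add_nodes(graph, data.frame(
          node_id = cid, component = "compound", role = "enriched",
          display_name = nm, provenance = "bioactivity-pool",
          stringsAsFactors = FALSE))
      }
      rec <- pool$records[pool$records$compound_id == cid &
                          pool$records$target_protein_id %in% gp, , drop = FALSE]
      if (nrow(rec) > 0L) {
        w <- vapply(split(rec$pchembl, rec$target_protein_id), max, numeric(1))
        graph <- kg_add_edges(graph, data.frame(
          from = node, to = names(w), relation = "targets",
          evidence = "experimental", weight = unname(w),
          stringsAsFactors = FALSE))
      }
    }
  }

  ## (c) predicted DTIs --------------------------------------------------
  if (isTRUE(params$include_predictions)) {
    idx_pred <- build_annotation_index(ds, "compound-predicted")
    ranked <- rank_component_terms(gp, idx_pred,
                                   exclusions = c(query_ids,
                                                  graph$nodes$node_id))
    ranked <- apply_ligand_thresholds(ranked, params)
    present <- graph_present_compounds(graph, ds)
    # predicted ligands spend the remaining per-component node budget, so
    # the k-cap holds over approved + experimental + predicted additions
    budget <- c(
      drug = max(0L, params$k[["drug"]] -
                   sum(graph$nodes$component == "drug" &
                       graph$nodes$role != "query")),
      compound = max(0L, params$k[["compound"]] -
                       sum(graph$nodes$component == "compound" &
                           graph$nodes$role != "query")))
    if (nrow(ranked) > 0L && sum(budget) > 0L) {
      cl <- cluster_for_selection(ds, ranked$term_id, present, params)
      taken <- unname(cl$assignment[intersect(present, names(cl$assignment))])
      sel <- integer(0)
      for (i in seq_len(nrow(ranked))) {
        if (sum(budget) <= 0L) break
        cid <- ranked$term_id[i]
        comp_i <- if (cid %in% ds$drugs$drug_id) "drug" else "compound"
        if (budget[[comp_i]] <= 0L) next
        cl_i <- cl$assignment[[cid]]
        if (cl_i %in% taken) next
        taken <- c(taken, cl_i)
        sel <- c(sel, i)
        budget[[comp_i]] <- budget[[comp_i]] - 1L
      }
      chosen <- ranked[sel, , drop = FALSE]
    } else chosen <- ranked[0, , drop = FALSE]
    graph$report[["compound-predicted"]] <-
      report_table(ds, "compound", ranked, chosen$term_id)
    pd <- ds$predicted_dtis
    for (cid in chosen$term_id) {
      is_drug <- cid %in% ds$drugs$drug_id
      nm <- if (is_drug) ds$drugs$name[match(cid, ds$drugs$drug_id)]
            else ds$compounds$name[match(cid, ds$compounds$compound_id)]
      graph <- kg_add_nodes(graph, data.frame(
        node_id = cid, component = if (is_drug) "drug" else "compound",
        role = "enriched",
        display_name = if (length(nm) == 0L || is.na(nm)) cid else nm,
        provenance = "predicted-dti", stringsAsFactors = FALSE))
      rec <- pd[pd$compound_or_drug_id == cid &
                pd$target_protein_id %in% gp, , drop = FALSE]
      if (nrow(rec) > 0L) {
        sc <- vapply(split(rec$score, rec$target_protein_id),
                     function(v) if (all(is.na(v))) NA_real_ else
                       max(v, na.rm = TRUE), numeric(1))
        graph <- kg_add_edges(graph, data.frame(
          from = cid, to = names(sc), relation = "targets",
          evidence = "predicted", weight = unname(sc),
          stringsAsFactors = FALSE))
      }
    }
  }
  graph
}

#' Collapse multi-evidence target edges and add secondary-evidence edges
#'
#' For every (ligand, protein) pair carrying several `targets` edges, only
#' the highest-priority evidence survives (approved > experimental >
#' predicted). Then, for every drug node, experimental bioactivities of its
#' compound cross-reference and predicted DTIs (of the drug id or its
#' cross-reference) to graph proteins not already covered are added as new
#' edges; compound nodes likewise gain their additional predicted edges.
#' The operation is idempotent.
#'
#' @param graph a `kg_graph` with merged nodes resolved.
#' @param ds a filtered `kg_datastore` view.
#' @param params a `kg_build_params` (evidence toggles are honoured).
#' @return the reconciled `kg_graph`.
#' @export
reconcile_edge_labels <- function(graph, ds, params = graph$params) {
  params <- params %||% build_params()
  gp <- kg_graph_proteins(graph)

  ## edge addition ------------------------------------------------------
  drug_nodes <- graph$nodes$node_id[graph$nodes$component == "drug"]
  comp_nodes <- graph$nodes$node_id[graph$nodes$component == "compound"]
  add <- empty_edges()
  if (isTRUE(params$include_experimental) && length(drug_nodes) > 0L) {
    ba <- filter_bioactivities(ds$bioactivities, taxa = NULL,
                               pchembl_min = params$pool_floor)
    xref <- ds$drugs$compound_xref[match(drug_nodes, ds$drugs$drug_id)]
    for (i in seq_along(drug_nodes)) {
      if (is.na(xref[i])) next
      rec <- ba[ba$compound_id == xref[i] & ba$target_protein_id %in% gp,
                , drop = FALSE]
      if (nrow(rec) == 0L) next
      w <- vapply(split(rec$pchembl, rec$target_protein_id), max, numeric(1))
      add <- rbind(add, data.frame(
        from = drug_nodes[i], to = names(w), relation = "targets",
        evidence = "experimental", weight = unname(w),
        stringsAsFactors = FALSE))
    }
  }
  if (isTRUE(params$include_predictions) &&
      length(c(drug_nodes, comp_nodes)) > 0L) {
    pd <- ds$predicted_dtis
    xref <- ds$drugs$compound_xref[match(drug_nodes, ds$drugs$drug_id)]
    lig_alias <- c(stats::setNames(drug_nodes, drug_nodes),
                   stats::setNames(drug_nodes, ifelse(is.na(xref), "",
                                                      xref)),
                   stats::setNames(comp_nodes, comp_nodes))
    lig_alias <- lig_alias[nzchar(names(lig_alias))]
    hit <- pd$compound_or_drug_id %in% names(lig_alias) &
           pd$target_protein_id %in% gp
    rec <- pd[hit, , drop = FALSE]
    if (nrow(rec) > 0L) {
      node <- unname(lig_alias[rec$compound_or_drug_id])
      key <- paste(node, rec$target_protein_id, sep = "\r")
      sc <- vapply(split(rec$score, key),
                   function(v) if (all(is.na(v))) NA_real_ else
                     max(v, na.rm = TRUE), numeric(1))
      parts <- strsplit(names(sc), "\r", fixed = TRUE)
      add <- rbind(add, data.frame(
        from = vapply(parts, `[`, character(1), 1L),
        to = vapply(parts, `[`, character(1), 2L),
        relation = "targets", evidence = "predicted", weight = unname(sc),
        stringsAsFactors = FALSE))
    }
  }
  if (nrow(add) > 0L) graph <- kg_add_edges(graph, add)

  ## priority collapse --------------------------------------------------
  e <- graph$edges
  is_t <- e$relation == "targets"
  te <- e[is_t, , drop = FALSE]
  if (nrow(te) > 0L) {
    prio <- match(te$evidence, EVIDENCE_LEVELS)  # 1 best
    ord <- order_radix(te$from, te$to, prio)
    te <- te[ord, , drop = FALSE]
    keep <- !duplicated(paste(te$from, te$to, sep = "\r"))
    graph$edges <- rbind(e[!is_t, , drop = FALSE], te[keep, , drop = FALSE])
    rownames(graph$edges) <- NULL
  }
  graph
}

#' Add cross-component relation edges
#'
#' Adds `indicates` (drug to disease, from drug indications), `modulates`
#' (disease to pathway) and `is associated with` (disease to phenotype)
#' edges wherever both endpoints are in the graph and the datastore records
#' the relation.
#'
#' @param graph a `kg_graph` with all nodes placed.
#' @param ds a `kg_datastore`.
#' @return the extended `kg_graph`.
#' @export
attach_cross_component_edges <- function(graph, ds) {
  nodes_of <- function(comp) graph$nodes$node_id[graph$nodes$component == comp]
  drugs <- nodes_of("drug"); diseases <- nodes_of("disease")
  pathways <- nodes_of("pathway"); phenos <- nodes_of("phenotype")
  add <- empty_edges()
  if (length(drugs) > 0L && length(diseases) > 0L) {
    ind <- ds$drugs$indication_disease_ids[match(drugs, ds$drugs$drug_id)]
    for (i in seq_along(drugs)) {
      hit <- intersect(ind[[i]] %||% character(0), diseases)
      if (length(hit) > 0L)
        add <- rbind(add, data.frame(from = drugs[i], to = hit,
                                     relation = "indicates",
                                     evidence = NA_character_,
                                     weight = NA_real_,
                                     stringsAsFactors = FALSE))
    }
  }
  if (length(diseases) > 0L) {
    i <- match(diseases, ds$terms$term_id[ds$terms$component == "disease"])
    dtab <- ds$terms[ds$terms$component == "disease", , drop = FALSE]
    for (j in seq_along(diseases)) {
      if (is.na(i[j])) next
      pw <- intersect(dtab$pathway_ids[[i[j]]], pathways)
      if (length(pw) > 0L)
        add <- rbind(add, data.frame(from = diseases[j], to = pw,
                                     relation = "modulates",
                                     evidence = NA_character_,
                                     weight = NA_real_,
                                     stringsAsFactors = FALSE))
      ph <- intersect(dtab$phenotype_ids[[i[j]]], phenos)
      if (length(ph) > 0L)
        add <- rbind(add, data.frame(from = diseases[j], to = ph,
                                     relation = "is associated with",
                                     evidence = NA_character_,
                                     weight = NA_real_,
                                     stringsAsFactors = FALSE))
    }
  }
  if (nrow(add) > 0L) graph <- kg_add_edges(graph, add)
  graph
}

#' Build a knowledge graph from a query
#'
#' Runs the full construction workflow: taxon/review filtering, query
#' resolution, core-protein collection, PPI neighbour expansion,
#' enrichment-filtered addition of pathways, phenotypes and diseases,
#' ligand incorporation (drugs, experimental compounds, predicted DTIs),
#' evidence-priority edge reconciliation, cross-component edges, and
#' pruning of degree-0 non-query nodes. The result is deterministic for a
#' given (query, datastore, params).
#'
#' @param query a `kg_query` (see [query_spec()]).
#' @param ds a `kg_datastore` (unfiltered; the taxon/review filter in
#'   `params` is applied internally).
#' @param params a `kg_build_params`.
#' @return a canonical `kg_graph` with per-component report tables
#'   (enrichment scores and significance for the top 100 candidates).
#' @export
build_knowledge_graph <- function(query, ds, params = build_params()) {
  stopifnot(inherits(query, "kg_query"), inherits(ds, "kg_datastore"))
  view <- filter_proteins_by_taxon(ds, params$taxa, params$reviewed_only,
                                   params$allow_unreviewed)
  core <- collect_core_proteins(query, view)
  rq <- attr(core, "resolved")
  prov <- attr(core, "provenance")
  if (length(core) == 0L)
    stop_kg("no core proteins after filtering; nothing to build on")

  graph <- new_kg_graph(query = rq, params = params)

  ## query anchors ------------------------------------------------------
  graph <- kg_add_nodes(graph, data.frame(
    node_id = rq$term_id, component = rq$component, role = "query",
    display_name = rq$display_name, provenance = "query",
    stringsAsFactors = FALSE))

  ## core + neighbour proteins ------------------------------------------
  neigh <- expand_neighbours(core, view, k = params$k[["gene/protein"]])
  graph$report[["gene/protein"]] <-
    report_table(view, "gene/protein", attr(neigh, "ranking") %||%
                   rank_component_terms(character(0), list(), N = 1L), neigh)
  prot <- setdiff(c(core, neigh), rq$term_id)  # query gene nodes exist already
  if (length(prot) > 0L) {
    role <- ifelse(prot %in% core, "core_protein", "neighbour_protein")
    sym <- view$proteins$gene_symbol[match(prot, view$proteins$protein_id)]
    graph <- kg_add_nodes(graph, data.frame(
      node_id = prot, component = "gene/protein", role = role,
      display_name = sym,
      provenance = ifelse(prot %in% core, "core", "ppi-expansion"),
      stringsAsFactors = FALSE))
  }

  ## PPI edges among graph proteins (canonical a < b) --------------------
  gp <- kg_graph_proteins(graph)
  pe <- view$ppis[view$ppis$protein_a %in% gp & view$ppis$protein_b %in% gp,
                  , drop = FALSE]
  if (nrow(pe) > 0L)
    graph <- kg_add_edges(graph, data.frame(
      from = pmin(pe$protein_a, pe$protein_b),
      to = pmax(pe$protein_a, pe$protein_b),
      relation = "interacts with", evidence = NA_character_,
      weight = pe$confidence, stringsAsFactors = FALSE))

  ## non-protein query terms: association edges to graph proteins --------
  for (i in seq_len(nrow(rq))) {
    comp <- rq$component[i]; tid <- rq$term_id[i]
    assoc <- intersect(prov[[tid]], gp)
    if (comp %in% TERM_COMPONENTS) {
      graph <- kg_add_edges(graph, term_protein_edges(graph, view, comp, tid))
    } else if (comp == "drug" && length(assoc) > 0L) {
      graph <- kg_add_edges(graph, data.frame(
        from = tid, to = assoc, relation = "targets", evidence = "approved",
        weight = NA_real_, stringsAsFactors = FALSE))
    } else if (comp == "compound" && length(assoc) > 0L) {
      exp_t <- intersect(
        view$annotation_index[["compound-experimental"]][[tid]] %||% character(0),
        gp)
      if (length(exp_t) > 0L)
        graph <- kg_add_edges(graph, data.frame(
          from = tid, to = exp_t, relation = "targets",
          evidence = "experimental", weight = NA_real_,
          stringsAsFactors = FALSE))
      prd_t <- setdiff(intersect(
        view$annotation_index[["compound-predicted"]][[tid]] %||% character(0),
        gp), exp_t)
      if (length(prd_t) > 0L)
        graph <- kg_add_edges(graph, data.frame(
          from = tid, to = prd_t, relation = "targets",
          evidence = "predicted", weight = NA_real_,
          stringsAsFactors = FALSE))
    }
  }

  ## enriched terms, ligands, reconciliation, cross edges ----------------
  for (comp in c("pathway", "phenotype", "disease"))
    graph <- add_enriched_terms(graph, comp, view, k = params$k[[comp]])
  graph <- incorporate_ligands(graph, view, params)
  graph <- reconcile_edge_labels(graph, view, params)
  graph <- attach_cross_component_edges(graph, view)
  graph <- kg_prune(graph)
  kg_canonicalize(graph)
}
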