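# Synthetic datastore generator.
#
# Emulates the *structure* of the real collections, not their content:
# proteins fall into functional modules; specific terms annotate inside
# one module (small M, correlated with PPIs), hub terms annotate a large
# fraction of all proteins (M close to N); compounds carry planted
# scaffold clusters with controlled within/between Tanimoto similarity;
# pChEMBL values span the activity filter and the iterative cutoff scan.
# Everything is reproducible from the seed and ships with a ground-truth
# manifest (planted hubs, planted clusters, expected query cores).

# Run code under a private RNG stream, restoring the caller's state.
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  force(code)
}

#' Synthetic datastore parameters
#'
#' Defaults describe a desk-scale datastore: 200 proteins in 10 functional
#' modules (85% human, 5% unreviewed), a PPI network with mean degree 4
#' concentrated within modules plus 2 promiscuous hub proteins, 15
#' module-specific terms per module per ontology component (each
#' annotating 8 module proteins) plus 2 planted hub terms per component
#' annotating 80% of all proteins, 150 module-specific drugs plus 2 hub
#' drugs, and 60 compounds in 10 planted scaffold clusters with expected
#' within-cluster Tanimoto 0.7 (between-cluster pairs stay far below the
#' 0.5 clustering threshold). pChEMBL values are uniform on \[4, 10\] so
#' both the activity floor (5) and the iterative cutoff scan have bite.
#'
#' @param n_proteins,n_modules protein count and module count.
#' @param taxa_mix named fractions per taxon (names are taxon ids).
#' @param unreviewed_fraction fraction of unreviewed protein entries.
#' @param ppi_mean_degree mean PPI degree of non-hub proteins.
#' @param ppi_within_module probability a PPI partner is module-internal.
#' @param n_ppi_hub_proteins,ppi_hub_degree_fraction planted promiscuous
#'   proteins and the fraction of the proteome each touches.
#' @param terms_per_module named counts of module-specific terms per
#'   component (`disease`, `pathway`, `phenotype`).
#' @param term_annotation_size proteins annotated by one specific term.
#' @param n_hub_terms hub terms per ontology component.
#' @param hub_fraction fraction of all proteins a hub term annotates.
#' @param n_drugs_per_module,drug_targets,n_hub_drugs drug table shape.
#' @param n_drug_xrefs drugs cross-referenced to a compound entry.
#' @param n_compounds,n_scaffold_clusters compound count and planted
#'   cluster count.
#' @param fp_width,fp_bits fingerprint width and on-bit count.
#' @param within_cluster_tanimoto target expected Tanimoto between two
#'   members of one cluster.
#' @param between_cluster_tanimoto upper target for cross-cluster pairs.
#' @param bioactivities_per_compound mean bioactivity records per
#'   compound.
#' @param pchembl_range uniform range of generated pChEMBL values.
#' @param pchembl_missing_rate,offtype_rate,nonsingle_rate rates of
#'   records lacking a pChEMBL value, carrying a non-comparable standard
#'   type, or targeting a non-single-protein entity.
#' @param n_predicted_dtis predicted drug/compound-target rows.
#' @param cross_relation_prob probability a disease term records a
#'   module pathway (and phenotype) relation.
#' @param phenotype_parent_prob probability a phenotype term has its
#'   module predecessor as ontology parent.
#' @param focus_gene_diseases when > 0, plant a focus gene annotated with
#'   this many dedicated disease terms of varying M (for query-cap
#'   studies).
#' @param rng_seed integer seed; generation is fully reproducible.
#' @return a `kg_synth_params` list.
#' @export
synth_params <- function(n_proteins = 200L, n_modules = 10L,
                         taxa_mix = c(`9606` = 0.85, `10090` = 0.15),
                         unreviewed_fraction = 0.05,
                         ppi_mean_degree = 4,
                         ppi_within_module = 0.9,
                         n_ppi_hub_proteins = 2L,
                         ppi_hub_degree_fraction = 0.5,
                         terms_per_module = c(disease = 15L, pathway = 15L,
                                              phenotype = 15L),
                         term_annotation_size = 8L,
                         n_hub_terms = 2L, hub_fraction = 0.8,
                         n_drugs_per_module = 15L, drug_targets = 4L,
                         n_hub_drugs = 2L, n_drug_xrefs = 5L,
                         n_compounds = 60L, n_scaffold_clusters = 10L,
                         fp_width = 1024L, fp_bits = 64L,
                         within_cluster_tanimoto = 0.7,
                         between_cluster_tanimoto = 0.3,
                         bioactivities_per_compound = 3,
                         pchembl_range = c(4, 10),
                         pchembl_missing_rate = 0.05,
                         offtype_rate = 0.05, nonsingle_rate = 0.05,
                         n_predicted_dtis = 120L,
                         cross_relation_prob = 0.3,
                         phenotype_parent_prob = 0.3,
                         focus_gene_diseases = 0L,
                         rng_seed = 1L) {
  stopifnot(n_proteins > 0, n_modules > 0, n_modules <= n_proteins,
            hub_fraction >= 0, hub_fraction <= 1,
            within_cluster_tanimoto > between_cluster_tanimoto,
            within_cluster_tanimoto <= 1, between_cluster_tanimoto >= 0,
            all(terms_per_module >= 0),
            n_scaffold_clusters <= n_compounds || n_compounds == 0)
  p <- as.list(environment())
  structure(p, class = "kg_synth_params")
}

# Member fingerprint: replace a fraction f of the seed scaffold's on-bits
# with fresh bits, keeping the on-bit count. Two members then share an
# expected (1-f)^2 of the scaffold, giving expected pairwise Tanimoto
# (1-f)^2 / (2 - (1-f)^2); inverting for the requested within-cluster
# similarity t gives (1-f)^2 = 2t/(1+t).
scaffold_member <- function(scaffold, f, width) {
  n_flip <- round(f * length(scaffold))
  if (n_flip == 0L) return(sort(scaffold))
  drop <- sample(length(scaffold), n_flip)
  fresh <- sample(setdiff(seq_len(width) - 1L, scaffold), n_flip)
  sort(c(scaffold[-drop], fresh))
}

fmt_ids <- function(prefix, n) sprintf("%s%04d", prefix, seq_len(n))

#' Generate a synthetic datastore
#'
#' Writes the seven collection TSVs, `manifest.json` and
#' `ground_truth.json` (planted hub terms/drugs/proteins, planted scaffold
#' clusters, module assignment, expected core proteins per disease term)
#' into `dir`. Byte-identical across runs with the same parameters.
#'
#' @param params a [synth_params()] object.
#' @param dir output directory (created if needed).
#' @return invisibly, a list with `manifest`, `ground_truth` and `dir`.
#' @seealso [synth_datastore()] to generate and load in one step.
#' @export
generate_datastore <- function(params = synth_params(), dir) {
  stopifnot(inherits(params, "kg_synth_params"))
  p <- params
  with_seed(p$rng_seed, {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)

    ## proteins ---------------------------------------------------------
    pid <- fmt_ids("P", p$n_proteins)
    taxa <- as.integer(names(p$taxa_mix))
    taxon <- taxa[sample.int(length(taxa), p$n_proteins, replace = TRUE,
                             prob = p$taxa_mix)]
    reviewed <- stats::runif(p$n_proteins) >= p$unreviewed_fraction
    module <- ((seq_len(p$n_proteins) - 1L) %% p$n_modules) + 1L
    if (p$focus_gene_diseases > 0L) {
      taxon[1L] <- taxa[1L]
      reviewed[1L] <- TRUE
    }
    mod_members <- split(pid, module)

    ## ontology terms ---------------------------------------------------
    prefixes <- c(disease = "DIS", pathway = "PWY", phenotype = "HPO")
    term_rows <- list()
    annot <- list(disease = list(), pathway = list(), phenotype = list())
    hub_terms <- list()
    term_module <- list()
    for (comp in names(prefixes)) {
      n_spec <- p$terms_per_module[[comp]] * p$n_modules
      ids <- fmt_ids(prefixes[[comp]], n_spec)
      mods <- rep(seq_len(p$n_modules), each = p$terms_per_module[[comp]])
      for (i in seq_along(ids)) {
        pool <- mod_members[[mods[i]]]
        annot[[comp]][[ids[i]]] <-
          sort(sample(pool, min(p$term_annotation_size, length(pool))))
      }
      hubs <- if (p$n_hub_terms > 0L)
        sprintf("%sHUB%02d", prefixes[[comp]], seq_len(p$n_hub_terms))
      else character(0)
      for (h in hubs)
        annot[[comp]][[h]] <-
          sort(sample(pid, round(p$hub_fraction * p$n_proteins)))
      hub_terms[[comp]] <- hubs
      term_module[[comp]] <- stats::setNames(mods, ids)
      all_ids <- c(ids, hubs)
      parent <- rep("", length(all_ids))
      if (comp == "phenotype" && p$terms_per_module[[comp]] > 1L) {
        # shallow within-module chains to exercise parent-child thinning
        for (i in seq_along(ids)) {
          within <- (i - 1L) %% p$terms_per_module[[comp]]
          if (within > 0L && stats::runif(1) < p$phenotype_parent_prob)
            parent[i] <- ids[i - 1L]
        }
      }
      term_rows[[comp]] <- data.frame(
        term_id = all_ids, component = comp,
        name = paste0(tolower(comp), " term ", all_ids),
        source = ifelse(grepl("HUB", all_ids), "synthetic-hub", "synthetic"),
        parent_ids = parent, pathway_ids = "", phenotype_ids = "",
        stringsAsFactors = FALSE)
    }

    ## focus gene extra diseases (varying M) -----------------------------
    focus <- NULL
    if (p$focus_gene_diseases > 0L) {
      ids <- sprintf("FOC%04d", seq_len(p$focus_gene_diseases))
      for (j in seq_along(ids)) {
        extra <- sample(setdiff(pid, pid[1L]), 2L + (j %% 10L))
        annot$disease[[ids[j]]] <- sort(c(pid[1L], extra))
      }
      term_rows$disease <- rbind(term_rows$disease, data.frame(
        term_id = ids, component = "disease",
        name = paste0("focus disease ", ids), source = "synthetic-focus",
        parent_ids = "", pathway_ids = "", phenotype_ids = "",
        stringsAsFactors = FALSE))
      focus <- list(protein = pid[1L], diseases = ids)
    }

    ## disease cross-relations to module pathways/phenotypes -------------
    dis_ids <- names(term_module$disease)
    for (i in seq_along(dis_ids)) {
      if (stats::runif(1) >= p$cross_relation_prob) next
      mod <- term_module$disease[[dis_ids[i]]]
      pw_pool <- names(term_module$pathway)[term_module$pathway == mod]
      ph_pool <- names(term_module$phenotype)[term_module$phenotype == mod]
      row <- match(dis_ids[i], term_rows$disease$term_id)
      if (length(pw_pool) > 0L)
        term_rows$disease$pathway_ids[row] <- sample(pw_pool, 1L)
      if (length(ph_pool) > 0L)
        term_rows$disease$phenotype_ids[row] <- sample(ph_pool, 1L)
    }
    terms_df <- do.call(rbind, term_rows)

    ## per-protein annotation columns ------------------------------------
    inv <- function(comp) {
      per <- stats::setNames(vector("list", p$n_proteins), pid)
      for (tid in names(annot[[comp]]))
        for (pr in annot[[comp]][[tid]])
          per[[pr]] <- c(per[[pr]], tid)
      vapply(per, function(v) paste(sort(v), collapse = "|"), character(1))
    }
    proteins_df <- data.frame(
      protein_id = pid, gene_symbol = paste0("G", sub("^P", "", pid)),
      taxon_id = taxon, reviewed = tolower(as.character(reviewed)),
      disease_ids = inv("disease"), pathway_ids = inv("pathway"),
      phenotype_ids = inv("phenotype"), stringsAsFactors = FALSE)

    ## PPIs ---------------------------------------------------------------
    # hub proteins sit at the end of the id range so they never collide
    # with the focus gene (always the first protein)
    hub_prot <- if (p$n_ppi_hub_proteins > 0L)
      rev(pid)[seq_len(p$n_ppi_hub_proteins)] else character(0)
    edges_a <- character(0); edges_b <- character(0)
    for (i in seq_len(p$n_proteins)) {
      deg <- stats::rpois(1, p$ppi_mean_degree / 2)
      if (deg == 0L) next
      within <- stats::runif(deg) < p$ppi_within_module
      pool_in <- setdiff(mod_members[[module[i]]], pid[i])
      pool_out <- setdiff(pid, mod_members[[module[i]]])
      partners <- character(0)
      if (any(within) && length(pool_in) > 0L)
        partners <- c(partners, sample(pool_in, min(sum(within),
                                                    length(pool_in))))
      if (any(!within) && length(pool_out) > 0L)
        partners <- c(partners, sample(pool_out, min(sum(!within),
                                                     length(pool_out))))
      edges_a <- c(edges_a, rep(pid[i], length(partners)))
      edges_b <- c(edges_b, partners)
    }
    for (h in hub_prot) {
      tied <- sample(setdiff(pid, h),
                     round(p$ppi_hub_degree_fraction * p$n_proteins))
      edges_a <- c(edges_a, rep(h, length(tied)))
      edges_b <- c(edges_b, tied)
    }
    a <- pmin(edges_a, edges_b); b <- pmax(edges_a, edges_b)
    keep <- !duplicated(paste(a, b)) & a != b
    ppis_df <- data.frame(protein_a = a[keep], protein_b = b[keep],
                          confidence = round(stats::runif(sum(keep), 0.2, 1),
                                             3),
                          stringsAsFactors = FALSE)
    ppis_df <- ppis_df[order_radix(ppis_df$protein_a, ppis_df$protein_b),
                       , drop = FALSE]

    ## compounds with planted scaffold clusters ---------------------------
    n_cl <- if (p$n_compounds > 0L) p$n_scaffold_clusters else 0L
    cid <- fmt_ids("CPD", p$n_compounds)
    cluster_of <- if (p$n_compounds > 0L)
      rep(seq_len(max(n_cl, 1L)), length.out = p$n_compounds) else integer(0)
    cluster_of <- sort(cluster_of)
    t_w <- p$within_cluster_tanimoto
    f <- 1 - sqrt(2 * t_w / (1 + t_w))
    fps <- vector("list", p$n_compounds)
    scaffolds <- lapply(seq_len(n_cl), function(i)
      sort(sample(seq_len(p$fp_width) - 1L, p$fp_bits)))
    for (i in seq_len(p$n_compounds))
      fps[[i]] <- scaffold_member(scaffolds[[cluster_of[i]]], f, p$fp_width)
    compounds_df <- data.frame(
      compound_id = cid, name = paste0("compound ", cid),
      fingerprint = vapply(fps, paste, character(1), collapse = ","),
      fp_width = rep(p$fp_width, p$n_compounds), stringsAsFactors = FALSE)

    ## bioactivities ------------------------------------------------------
    cl_module <- if (n_cl > 0L)
      stats::setNames(rep(seq_len(p$n_modules), length.out = n_cl),
                      seq_len(n_cl)) else integer(0)
    ba_cpd <- vector("list", p$n_compounds)
    ba_tg <- vector("list", p$n_compounds)
    for (i in seq_len(p$n_compounds)) {
      mod <- cl_module[[as.character(cluster_of[i])]]
      n_rec <- stats::rpois(1, p$bioactivities_per_compound) + 1L
      tg <- sample(mod_members[[mod]], min(n_rec, length(mod_members[[mod]])))
      ba_cpd[[i]] <- rep(cid[i], length(tg))
      ba_tg[[i]] <- tg
    }
    ba_cpd <- unlist(ba_cpd); ba_tg <- unlist(ba_tg)
    n_ba <- length(ba_tg)
    if (is.null(n_ba) || n_ba == 0L) {
      bioactivities_df <- data.frame(
        compound_id = character(0), target_protein_id = character(0),
        standard_type = character(0), pchembl = character(0),
        target_kind = character(0), taxon_id = integer(0),
        stringsAsFactors = FALSE)
    } else {
      st <- ifelse(stats::runif(n_ba) < p$offtype_rate, "GI50",
                   sample(ALLOWED_STANDARD_TYPES, n_ba, replace = TRUE))
      pch <- round(stats::runif(n_ba, p$pchembl_range[1L],
                                p$pchembl_range[2L]), 2)
      pch[stats::runif(n_ba) < p$pchembl_missing_rate] <- NA_real_
      kind <- ifelse(stats::runif(n_ba) < p$nonsingle_rate, "complex",
                     "single_protein")
      bioactivities_df <- data.frame(
        compound_id = ba_cpd, target_protein_id = ba_tg, standard_type = st,
        pchembl = ifelse(is.na(pch), "",
                         vapply(pch, function(v)
                           if (is.na(v)) "" else format(v, trim = TRUE),
                           character(1))),
        target_kind = kind, taxon_id = taxon[match(ba_tg, pid)],
        stringsAsFactors = FALSE)
    }

    ## drugs ---------------------------------------------------------------
    n_drugs <- p$n_drugs_per_module * p$n_modules
    did <- fmt_ids("DRG", n_drugs)
    dmods <- rep(seq_len(p$n_modules), each = p$n_drugs_per_module)
    targets <- lapply(seq_len(n_drugs), function(i)
      sort(sample(mod_members[[dmods[i]]],
                  min(p$drug_targets, length(mod_members[[dmods[i]]])))))
    indications <- vapply(seq_len(n_drugs), function(i) {
      if (stats::runif(1) >= 0.5) return("")
      pool <- names(term_module$disease)[term_module$disease == dmods[i]]
      if (length(pool) == 0L) "" else sample(pool, 1L)
    }, character(1))
    hub_drug_ids <- if (p$n_hub_drugs > 0L)
      sprintf("DRGHUB%02d", seq_len(p$n_hub_drugs)) else character(0)
    hub_targets <- lapply(hub_drug_ids, function(h)
      sort(sample(pid, round(p$hub_fraction * p$n_proteins))))
    xref <- rep("", n_drugs)
    n_x <- min(p$n_drug_xrefs, n_drugs, p$n_compounds)
    if (n_x > 0L) xref[seq_len(n_x)] <- cid[seq_len(n_x)]
    drugs_df <- data.frame(
      drug_id = c(did, hub_drug_ids),
      name = paste0("drug ", c(did, hub_drug_ids)),
      status = sample(c("approved", "investigational"),
                      n_drugs + length(hub_drug_ids), replace = TRUE,
                      prob = c(0.7, 0.3)),
      target_protein_ids = c(vapply(targets, paste, character(1),
                                    collapse = "|"),
                             vapply(hub_targets, paste, character(1),
                                    collapse = "|")),
      indication_disease_ids = c(indications,
                                 rep("", length(hub_drug_ids))),
      compound_xref = c(xref, rep("", length(hub_drug_ids))),
      stringsAsFactors = FALSE)

    ## predicted DTIs -------------------------------------------------------
    n_pd <- p$n_predicted_dtis
    pd_src <- if (n_pd > 0L && (p$n_compounds > 0L || n_drugs > 0L)) {
      from_cpd <- stats::runif(n_pd) < 0.8 & p$n_compounds > 0L
      lig <- ifelse(from_cpd, sample(cid, n_pd, replace = TRUE),
                    sample(did, n_pd, replace = TRUE))
      tg <- sample(pid, n_pd, replace = TRUE)
      df <- data.frame(compound_or_drug_id = lig, target_protein_id = tg,
                       source_model = sample(c("cnn-dti", "pcm-dti"), n_pd,
                                             replace = TRUE),
                       score = format(round(stats::runif(n_pd), 3),
                                      trim = TRUE),
                       stringsAsFactors = FALSE)
      df[!duplicated(paste(df$compound_or_drug_id, df$target_protein_id)),
         , drop = FALSE]
    } else data.frame(compound_or_drug_id = character(0),
                      target_protein_id = character(0),
                      source_model = character(0), score = character(0),
                      stringsAsFactors = FALSE)

    ## write everything -----------------------------------------------------
    w <- function(df, name) {
      utils::write.table(df, file.path(dir, paste0(name, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE,
                         fileEncoding = "UTF-8")
      paste0(name, ".tsv")
    }
    man <- list(proteins = w(proteins_df, "proteins"),
                ppis = w(ppis_df, "ppis"),
                terms = w(terms_df, "terms"),
                drugs = w(drugs_df, "drugs"),
                compounds = w(compounds_df, "compounds"),
                bioactivities = w(bioactivities_df, "bioactivities"),
                predicted_dtis = w(pd_src, "predicted_dtis"))
    manifest <- file.path(dir, "manifest.json")
    jsonlite::write_json(man, manifest, auto_unbox = TRUE, pretty = TRUE)

    clusters_gt <- if (p$n_compounds > 0L)
      split(cid, cluster_of) else list()
    gt <- list(
      modules = split(pid, module),
      hub_terms = hub_terms,
      hub_drugs = hub_drug_ids,
      hub_proteins = hub_prot,
      scaffold_clusters = clusters_gt,
      focus = focus,
      expected_core = annot$disease,
      params = list(n_proteins = p$n_proteins, n_modules = p$n_modules,
                    hub_fraction = p$hub_fraction, rng_seed = p$rng_seed)
    )
    gt_path <- file.path(dir, "ground_truth.json")
    jsonlite::write_json(gt, gt_path, auto_unbox = TRUE, pretty = TRUE)
    invisible(list(dir = dir, manifest = manifest, ground_truth = gt_path))
  })
}

#' Generate and load a synthetic datastore in one step
#'
#' @param params a [synth_params()] object.
#' @param dir directory to generate into (default: a fresh temporary
#'   directory).
#' @return a `kg_datastore` with the ground truth attached as attribute
#'   `ground_truth`.
#' @export
synth_datastore <- function(params = synth_params(),
                            dir = tempfile("kgforge-synth-")) {
  paths <- generate_datastore(params, dir)
  ds <- load_datastore(paths$manifest, strict = TRUE)
  attr(ds, "ground_truth") <- jsonlite::read_json(paths$ground_truth,
                                                  simplifyVector = TRUE)
  ds
}

#' Sample a reproducible query set from a datastore
#'
#' Draws `n_per_component` single-term queries per component (only terms
#' with at least one protein association, so every query resolves and
#' yields a non-empty core) plus `combinatory` queries combining one term
#' from every component. Components with no eligible entries are skipped
#' with a warning.
#'
#' @param ds a `kg_datastore`.
#' @param n_per_component single-term queries per component.
#' @param combinatory number of combinatory queries.
#' @param seed RNG seed; sampling is reproducible.
#' @return a list of `kg_query` objects.
#' @export
generate_query_set <- function(ds, n_per_component = 2L, combinatory = 1L,
                               seed = 1L) {
  stopifnot(inherits(ds, "kg_datastore"))
  eligible <- list(
    "gene/protein" = ds$proteins$protein_id,
    "disease" = names(ds$annotation_index$disease),
    "pathway" = names(ds$annotation_index$pathway),
    "phenotype" = names(ds$annotation_index$phenotype),
    "drug" = names(ds$annotation_index$drug)[
      lengths(ds$annotation_index$drug) > 0L],
    "compound" = intersect(
      union(names(ds$annotation_index[["compound-experimental"]]),
            names(ds$annotation_index[["compound-predicted"]])),
      ds$compounds$compound_id)
  )
  with_seed(seed, {
    queries <- list()
    for (comp in names(eligible)) {
      pool <- eligible[[comp]]
      if (length(pool) == 0L) {
        warn_kg("component %s has no eligible query terms; skipped", comp)
        next
      }
      pick <- sample(pool, min(n_per_component, length(pool)))
      for (id in pick)
        queries[[length(queries) + 1L]] <-
          do.call(query_spec, stats::setNames(list(id), comp))
    }
    for (i in seq_len(combinatory)) {
      parts <- lapply(eligible, function(pool)
        if (length(pool) > 0L) sample(pool, 1L) else NULL)
      parts <- parts[!vapply(parts, is.null, logical(1))]
      queries[[length(queries) + 1L]] <- do.call(query_spec, parts)
    }
    queries
  })
}
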