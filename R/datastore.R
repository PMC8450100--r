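# Datastore: flat-file collections, validation, association indices, filters.
#
# The datastore is an in-memory view of seven TSV collections (proteins,
# PPIs, terms, drugs, compounds, bioactivities, predicted DTIs) plus the
# association indices every downstream stage consumes: per-component
# term -> protein mappings, a PPI adjacency index, and per-component totals
# (the N of the enrichment score).

KG_COMPONENTS <- c("gene/protein", "disease", "pathway", "phenotype",
                   "drug", "compound")
TERM_COMPONENTS <- c("disease", "pathway", "phenotype")
INDEX_COMPONENTS <- c("disease", "pathway", "phenotype", "drug",
                      "compound-experimental", "compound-predicted")

# Canonical column sets per collection (TSV headers).
DS_COLUMNS <- list(
  proteins       = c("protein_id", "gene_symbol", "taxon_id", "reviewed",
                     "disease_ids", "pathway_ids", "phenotype_ids"),
  ppis           = c("protein_a", "protein_b", "confidence"),
  terms          = c("term_id", "component", "name", "source", "parent_ids",
                     "pathway_ids", "phenotype_ids"),
  drugs          = c("drug_id", "name", "status", "target_protein_ids",
                     "indication_disease_ids", "compound_xref"),
  compounds      = c("compound_id", "name", "fingerprint", "fp_width"),
  bioactivities  = c("compound_id", "target_protein_id", "standard_type",
                     "pchembl", "target_kind", "taxon_id"),
  predicted_dtis = c("compound_or_drug_id", "target_protein_id",
                     "source_model", "score")
)

read_collection <- function(path, what) {
  if (!file.exists(path)) stop_kg("collection file not found: %s", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, quote = "",
                          colClasses = "character", na.strings = NULL,
                          check.names = FALSE)
  need <- DS_COLUMNS[[what]]
  # terms.tsv may omit the optional cross-relation columns
  optional <- if (what == "terms") c("pathway_ids", "phenotype_ids") else character(0)
  missing <- setdiff(setdiff(need, optional), names(df))
  if (length(missing) > 0L)
    stop_kg("%s: missing column(s): %s", path, paste(missing, collapse = ", "))
  for (opt in setdiff(optional, names(df))) df[[opt]] <- ""
  df[, need, drop = FALSE]
}

as_num <- function(x, what, col) {
  y <- suppressWarnings(as.numeric(x))
  bad <- !is.na(x) & is.na(y) & nzchar(x) & x != "NA"
  if (any(bad))
    stop_kg("%s: non-numeric value in column '%s' (e.g. '%s')",
            what, col, x[which(bad)[1L]])
  y
}

as_bool <- function(x, what, col) {
  y <- tolower(trimws(x)) %in% c("true", "1", "t", "yes")
  ok <- tolower(trimws(x)) %in% c("true", "false", "1", "0", "t", "f",
                                  "yes", "no")
  if (!all(ok))
    stop_kg("%s: non-boolean value in column '%s'", what, col)
  y
}

#' Load a flat-file datastore
#'
#' Reads the seven collection TSVs named by a JSON manifest (collection name
#' to file path, paths relative to the manifest unless absolute), validates
#' row types and identifier uniqueness, resolves cross-references, and
#' builds all association indices.
#'
#' Self-loop PPIs and duplicate unordered PPI pairs are dropped at load;
#' when duplicates disagree on confidence the maximum is kept. In strict
#' mode any unresolved cross-reference is an error; otherwise offending rows
#' are dropped and counted in the load log.
#'
#' @param manifest path to `manifest.json`, or a directory containing one.
#' @param strict logical; fail on unresolved cross-references (default
#'   `FALSE`: drop with a logged count).
#' @return an object of class `kg_datastore`; see [build_annotation_index()]
#'   for the index layout. The load log is in `$load_log`.
#' @seealso [write_datastore()], [filter_proteins_by_taxon()],
#'   [filter_ppis_by_confidence()]
#' @export
load_datastore <- function(manifest, strict = FALSE) {
  if (dir.exists(manifest)) manifest <- file.path(manifest, "manifest.json")
  if (!file.exists(manifest)) stop_kg("manifest not found: %s", manifest)
  man <- jsonlite::read_json(manifest, simplifyVector = TRUE)
  base <- dirname(manifest)
  path_of <- function(coll) {
    p <- man[[coll]]
    if (is.null(p)) stop_kg("manifest names no file for collection '%s'", coll)
    if (!grepl("^(/|[A-Za-z]:)", p)) p <- file.path(base, p)
    p
  }

  log <- list(dropped = integer(0))
  drop_note <- function(log, key, n) {
    if (n > 0L) {
      prev <- if (key %in% names(log$dropped)) log$dropped[[key]] else 0L
      log$dropped[key] <- prev + as.integer(n)
    }
    log
  }
  report <- function(key, n, msg) {
    if (n > 0L) {
      if (strict) stop_kg("strict load: %s (%d row(s))", msg, n)
      warn_kg("dropped %d row(s): %s", n, msg)
    }
  }
  # load-time cleanup (self-loops, duplicate pairs) always warns and
  # proceeds; strict mode only gates unresolved cross-references
  notify <- function(key, n, msg) {
    if (n > 0L) warn_kg("dropped %d row(s): %s", n, msg)
  }

  ## proteins -----------------------------------------------------------
  pr <- read_collection(path_of("proteins"), "proteins")
  if (anyDuplicated(pr$protein_id))
    stop_kg("duplicate protein_id in proteins collection")
  if (any(!nzchar(pr$protein_id)))
    stop_kg("empty protein_id in proteins collection")
  proteins <- data.frame(
    protein_id = pr$protein_id,
    gene_symbol = pr$gene_symbol,
    taxon_id = as.integer(as_num(pr$taxon_id, "proteins", "taxon_id")),
    reviewed = as_bool(pr$reviewed, "proteins", "reviewed"),
    stringsAsFactors = FALSE
  )
  if (any(is.na(proteins$taxon_id)) || any(proteins$taxon_id <= 0L))
    stop_kg("proteins: taxon_id must be a positive integer")
  proteins$disease_ids <- split_multi(pr$disease_ids)
  proteins$pathway_ids <- split_multi(pr$pathway_ids)
  proteins$phenotype_ids <- split_multi(pr$phenotype_ids)

  ## terms --------------------------------------------------------------
  tm <- read_collection(path_of("terms"), "terms")
  if (!all(tm$component %in% TERM_COMPONENTS))
    stop_kg("terms: component must be one of %s",
            paste(TERM_COMPONENTS, collapse = ", "))
  if (anyDuplicated(paste(tm$term_id, tm$component)))
    stop_kg("duplicate (term_id, component) in terms collection")
  terms <- data.frame(term_id = tm$term_id, component = tm$component,
                      name = tm$name, source = tm$source,
                      stringsAsFactors = FALSE)
  terms$parent_ids <- split_multi(tm$parent_ids)
  terms$pathway_ids <- split_multi(tm$pathway_ids)
  terms$phenotype_ids <- split_multi(tm$phenotype_ids)

  ## ppis ---------------------------------------------------------------
  pp <- read_collection(path_of("ppis"), "ppis")
  ppis <- data.frame(
    protein_a = pp$protein_a, protein_b = pp$protein_b,
    confidence = as_num(pp$confidence, "ppis", "confidence"),
    stringsAsFactors = FALSE
  )
  if (nrow(ppis) > 0L &&
      (any(is.na(ppis$confidence)) ||
       any(ppis$confidence < 0) || any(ppis$confidence > 1)))
    stop_kg("ppis: confidence must be in [0, 1]")
  n_self <- sum(ppis$protein_a == ppis$protein_b)
  notify("ppi_self_loops", n_self, "self-loop PPIs")
  log <- drop_note(log, "ppi_self_loops", n_self)
  ppis <- ppis[ppis$protein_a != ppis$protein_b, , drop = FALSE]
  # canonical unordered pair, keep max confidence among duplicates
  a <- pmin(ppis$protein_a, ppis$protein_b)
  b <- pmax(ppis$protein_a, ppis$protein_b)
  key <- paste(a, b, sep = "\r")
  n_dup <- sum(duplicated(key))
  notify("ppi_duplicates", n_dup,
         "duplicate unordered PPI pairs (max confidence kept)")
  log <- drop_note(log, "ppi_duplicates", n_dup)
  conf <- vapply(split(ppis$confidence, key), max, numeric(1))
  uk <- names(conf)
  parts <- strsplit(uk, "\r", fixed = TRUE)
  ppis <- data.frame(
    protein_a = vapply(parts, `[`, character(1), 1L),
    protein_b = vapply(parts, `[`, character(1), 2L),
    confidence = unname(conf),
    stringsAsFactors = FALSE
  )
  ppis <- ppis[order_radix(ppis$protein_a, ppis$protein_b), , drop = FALSE]
  rownames(ppis) <- NULL
  unknown <- !(ppis$protein_a %in% proteins$protein_id) |
             !(ppis$protein_b %in% proteins$protein_id)
  report("ppi_unknown_protein", sum(unknown), "PPIs referencing unknown proteins")
  log <- drop_note(log, "ppi_unknown_protein", sum(unknown))
  ppis <- ppis[!unknown, , drop = FALSE]

  ## drugs --------------------------------------------------------------
  dr <- read_collection(path_of("drugs"), "drugs")
  if (anyDuplicated(dr$drug_id)) stop_kg("duplicate drug_id in drugs collection")
  if (!all(dr$status %in% c("approved", "investigational")))
    stop_kg("drugs: status must be approved or investigational")
  drugs <- data.frame(drug_id = dr$drug_id, name = dr$name,
                      status = dr$status,
                      compound_xref = ifelse(nzchar(dr$compound_xref),
                                             dr$compound_xref, NA_character_),
                      stringsAsFactors = FALSE)
  drugs$target_protein_ids <- split_multi(dr$target_protein_ids)
  drugs$indication_disease_ids <- split_multi(dr$indication_disease_ids)

  ## compounds ----------------------------------------------------------
  cp <- read_collection(path_of("compounds"), "compounds")
  if (anyDuplicated(cp$compound_id))
    stop_kg("duplicate compound_id in compounds collection")
  compounds <- data.frame(compound_id = cp$compound_id, name = cp$name,
                          fp_width = as.integer(as_num(cp$fp_width,
                                                       "compounds", "fp_width")),
                          stringsAsFactors = FALSE)
  compounds$fingerprint <- lapply(strsplit(cp$fingerprint, ",", fixed = TRUE),
                                  function(v) sort(unique(as.integer(v[nzchar(v)]))))
  bad_fp <- mapply(function(fp, w) length(fp) > 0L && max(fp) >= w,
                   compounds$fingerprint, compounds$fp_width)
  if (length(bad_fp) > 0L && any(bad_fp))
    stop_kg("compounds: fingerprint on-bit position >= fp_width")

  ## bioactivities ------------------------------------------------------
  ba <- read_collection(path_of("bioactivities"), "bioactivities")
  bioactivities <- data.frame(
    compound_id = ba$compound_id,
    target_protein_id = ba$target_protein_id,
    standard_type = ba$standard_type,
    pchembl = as_num(ifelse(nzchar(ba$pchembl), ba$pchembl, NA_character_),
                     "bioactivities", "pchembl"),
    target_kind = ba$target_kind,
    taxon_id = as.integer(as_num(ba$taxon_id, "bioactivities", "taxon_id")),
    stringsAsFactors = FALSE
  )
  if (!all(bioactivities$target_kind %in% c("single_protein", "complex", "other")))
    stop_kg("bioactivities: target_kind must be single_protein, complex or other")
  if (any(!is.na(bioactivities$pchembl) & bioactivities$pchembl <= 0))
    stop_kg("bioactivities: pchembl, when present, must be > 0")

  ## predicted DTIs -----------------------------------------------------
  pd <- read_collection(path_of("predicted_dtis"), "predicted_dtis")
  predicted_dtis <- data.frame(
    compound_or_drug_id = pd$compound_or_drug_id,
    target_protein_id = pd$target_protein_id,
    source_model = pd$source_model,
    score = as_num(ifelse(nzchar(pd$score), pd$score, NA_character_),
                   "predicted_dtis", "score"),
    stringsAsFactors = FALSE
  )

  ## cross-reference resolution -----------------------------------------
  term_key <- function(component) terms$term_id[terms$component == component]
  prot_ids <- proteins$protein_id
  cpd_ids <- compounds$compound_id

  scrub_list <- function(lst, universe, key, msg) {
    n_bad <- sum(vapply(lst, function(v) sum(!(v %in% universe)), 0L))
    report(key, n_bad, msg)
    if (n_bad > 0L) lst <- lapply(lst, function(v) v[v %in% universe])
    list(lst = lst, n = n_bad)
  }
  for (comp in TERM_COMPONENTS) {
    col <- paste0(sub("disease", "disease", comp), "_ids")
    sc <- scrub_list(proteins[[col]], term_key(comp), paste0("protein_", comp),
                     sprintf("protein %s annotations to unknown terms", comp))
    proteins[[col]] <- sc$lst
    log <- drop_note(log, paste0("protein_", comp, "_unknown_term"), sc$n)
  }
  sc <- scrub_list(drugs$target_protein_ids, prot_ids, "drug_targets",
                   "drug target references to unknown proteins")
  drugs$target_protein_ids <- sc$lst
  log <- drop_note(log, "drug_unknown_target", sc$n)
  sc <- scrub_list(drugs$indication_disease_ids, term_key("disease"),
                   "drug_indications", "drug indications to unknown diseases")
  drugs$indication_disease_ids <- sc$lst
  log <- drop_note(log, "drug_unknown_indication", sc$n)

  bad_xref <- !is.na(drugs$compound_xref) & !(drugs$compound_xref %in% cpd_ids)
  report("drug_xref", sum(bad_xref), "drug compound_xref to unknown compounds")
  log <- drop_note(log, "drug_unknown_xref", sum(bad_xref))
  drugs$compound_xref[bad_xref] <- NA_character_

  bad_ba <- !(bioactivities$compound_id %in% cpd_ids) |
            !(bioactivities$target_protein_id %in% prot_ids)
  report("bioactivity_refs", sum(bad_ba),
         "bioactivities referencing unknown compounds/proteins")
  log <- drop_note(log, "bioactivity_unknown_ref", sum(bad_ba))
  bioactivities <- bioactivities[!bad_ba, , drop = FALSE]

  bad_pd <- !(predicted_dtis$compound_or_drug_id %in% c(cpd_ids, drugs$drug_id)) |
            !(predicted_dtis$target_protein_id %in% prot_ids)
  report("predicted_dti_refs", sum(bad_pd),
         "predicted DTIs referencing unknown entities")
  log <- drop_note(log, "predicted_dti_unknown_ref", sum(bad_pd))
  predicted_dtis <- predicted_dtis[!bad_pd, , drop = FALSE]

  rownames(bioactivities) <- rownames(predicted_dtis) <- NULL

  ds <- structure(
    list(proteins = proteins, ppis = ppis, terms = terms, drugs = drugs,
         compounds = compounds, bioactivities = bioactivities,
         predicted_dtis = predicted_dtis, load_log = log),
    class = "kg_datastore"
  )
  rebuild_indices(ds)
}

# Recompute annotation_index / ppi_index / component_totals from the tables.
# Called after load and after every filter, so indices are always exact
# inverses of the visible tables.
rebuild_indices <- function(ds) {
  idx <- list()
  for (comp in TERM_COMPONENTS) {
    col <- paste0(comp, "_ids")
    ids <- rep(ds$proteins$protein_id, lengths(ds$proteins[[col]]))
    idx[[comp]] <- invert_relation(ids, unlist(ds$proteins[[col]]))
  }
  ids <- rep(ds$drugs$drug_id, lengths(ds$drugs$target_protein_ids))
  tg <- unlist(ds$drugs$target_protein_ids)
  idx[["drug"]] <- lapply(invert_relation(tg, ids), identity)

  # compound-experimental: canonical bioactivity filter (single-protein
  # targets, comparable standard types, pChEMBL present and >= 5)
  ba <- filter_bioactivities(ds$bioactivities,
                             taxa = unique(ds$proteins$taxon_id),
                             pchembl_min = 5)
  idx[["compound-experimental"]] <-
    invert_relation(ba$target_protein_id, ba$compound_id)
  idx[["compound-predicted"]] <-
    invert_relation(ds$predicted_dtis$target_protein_id,
                    ds$predicted_dtis$compound_or_drug_id)

  ppi_ids <- c(ds$ppis$protein_a, ds$ppis$protein_b)
  ppi_partners <- c(ds$ppis$protein_b, ds$ppis$protein_a)
  ds$ppi_index <- invert_relation(ppi_partners, ppi_ids)

  ds$annotation_index <- idx
  totals <- vapply(idx, function(m) length(unique(unlist(m))), 0L)
  totals["ppi"] <- length(ds$ppi_index)
  ds$component_totals <- totals
  ds
}

#' @export
print.kg_datastore <- function(x, ...) {
  cat("<kg_datastore>\n")
  cat(sprintf("  proteins: %d (taxa: %s)\n", nrow(x$proteins),
              paste(sort(unique(x$proteins$taxon_id)), collapse = ", ")))
  cat(sprintf("  ppis: %d   terms: %d   drugs: %d   compounds: %d\n",
              nrow(x$ppis), nrow(x$terms), nrow(x$drugs), nrow(x$compounds)))
  cat(sprintf("  bioactivities: %d   predicted DTIs: %d\n",
              nrow(x$bioactivities), nrow(x$predicted_dtis)))
  cat("  component totals:",
      paste(sprintf("%s=%d", names(x$component_totals), x$component_totals),
            collapse = " "), "\n")
  invisible(x)
}

#' Write a datastore back to TSV collections
#'
#' Serializes all seven collections plus `manifest.json` into `dir`, in the
#' same dialect [load_datastore()] reads (pipe-delimited multi-value cells).
#' `write_datastore(load_datastore(x))` reproduces `x` row-for-row.
#'
#' @param ds a `kg_datastore`.
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
write_datastore <- function(ds, dir) {
  stopifnot(inherits(ds, "kg_datastore"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) {
    path <- file.path(dir, paste0(name, ".tsv"))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
    paste0(name, ".tsv")
  }
  pr <- ds$proteins
  pr_out <- data.frame(protein_id = pr$protein_id, gene_symbol = pr$gene_symbol,
                       taxon_id = pr$taxon_id,
                       reviewed = tolower(as.character(pr$reviewed)),
                       disease_ids = join_multi(pr$disease_ids),
                       pathway_ids = join_multi(pr$pathway_ids),
                       phenotype_ids = join_multi(pr$phenotype_ids),
                       stringsAsFactors = FALSE)
  tm <- ds$terms
  tm_out <- data.frame(term_id = tm$term_id, component = tm$component,
                       name = tm$name, source = tm$source,
                       parent_ids = join_multi(tm$parent_ids),
                       pathway_ids = join_multi(tm$pathway_ids),
                       phenotype_ids = join_multi(tm$phenotype_ids),
                       stringsAsFactors = FALSE)
  dr <- ds$drugs
  dr_out <- data.frame(drug_id = dr$drug_id, name = dr$name, status = dr$status,
                       target_protein_ids = join_multi(dr$target_protein_ids),
                       indication_disease_ids = join_multi(dr$indication_disease_ids),
                       compound_xref = ifelse(is.na(dr$compound_xref), "",
                                              dr$compound_xref),
                       stringsAsFactors = FALSE)
  cp <- ds$compounds
  cp_out <- data.frame(compound_id = cp$compound_id, name = cp$name,
                       fingerprint = vapply(cp$fingerprint, paste,
                                            character(1), collapse = ","),
                       fp_width = cp$fp_width, stringsAsFactors = FALSE)
  ba <- ds$bioactivities
  ba_out <- ba
  ba_out$pchembl <- ifelse(is.na(ba$pchembl), "", format(ba$pchembl, trim = TRUE))
  pd <- ds$predicted_dtis
  pd_out <- pd
  pd_out$score <- ifelse(is.na(pd$score), "", format(pd$score, trim = TRUE))

  man <- list(proteins = w(pr_out, "proteins"),
              ppis = w(ds$ppis, "ppis"),
              terms = w(tm_out, "terms"),
              drugs = w(dr_out, "drugs"),
              compounds = w(cp_out, "compounds"),
              bioactivities = w(ba_out, "bioactivities"),
              predicted_dtis = w(pd_out, "predicted_dtis"))
  manifest <- file.path(dir, "manifest.json")
  jsonlite::write_json(man, manifest, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Association index for one component
#'
#' Returns the term -> protein-id mapping for a component, built over the
#' proteins currently visible in the datastore view. `attr(, "total")`
#' carries the component total N: the number of distinct visible proteins
#' with at least one association in that component.
#'
#' @param ds a `kg_datastore`.
#' @param component one of `disease`, `pathway`, `phenotype`, `drug`,
#'   `compound-experimental`, `compound-predicted`.
#' @return named list of character vectors, with attribute `total`.
#' @export
build_annotation_index <- function(ds, component) {
  stopifnot(inherits(ds, "kg_datastore"))
  if (!component %in% INDEX_COMPONENTS)
    stop_kg("unknown component '%s'; expected one of %s", component,
            paste(INDEX_COMPONENTS, collapse = ", "))
  idx <- ds$annotation_index[[component]]
  attr(idx, "total") <- unname(ds$component_totals[[component]])
  idx
}

#' Taxon / review-status protein filter
#'
#' Returns a datastore view restricted to proteins whose `taxon_id` is in
#' `taxa` and (when `reviewed_only`) whose entry is reviewed; an allow-list
#' can retain named unreviewed accessions. PPIs, bioactivities and predicted
#' DTIs that lose an endpoint are dropped and all indices are recomputed on
#' the view.
#'
#' @param ds a `kg_datastore`.
#' @param taxa non-empty vector of NCBI taxon identifiers (default human,
#'   9606).
#' @param reviewed_only keep only reviewed entries (default `TRUE`).
#' @param allow unreviewed accessions to retain regardless (default none).
#' @return a filtered `kg_datastore` view.
#' @export
filter_proteins_by_taxon <- function(ds, taxa = 9606L, reviewed_only = TRUE,
                                     allow = character(0)) {
  stopifnot(inherits(ds, "kg_datastore"))
  if (length(taxa) == 0L) stop_kg("taxa must be non-empty")
  keep <- ds$proteins$taxon_id %in% as.integer(taxa)
  if (reviewed_only)
    keep <- keep & (ds$proteins$reviewed | ds$proteins$protein_id %in% allow)
  view <- ds
  view$proteins <- ds$proteins[keep, , drop = FALSE]
  rownames(view$proteins) <- NULL
  ids <- view$proteins$protein_id
  if (length(ids) == 0L) warn_kg("taxon filter left zero proteins visible")
  view$ppis <- ds$ppis[ds$ppis$protein_a %in% ids & ds$ppis$protein_b %in% ids,
                       , drop = FALSE]
  view$bioactivities <-
    ds$bioactivities[ds$bioactivities$target_protein_id %in% ids, , drop = FALSE]
  view$predicted_dtis <-
    ds$predicted_dtis[ds$predicted_dtis$target_protein_id %in% ids, , drop = FALSE]
  view$drugs$target_protein_ids <-
    lapply(ds$drugs$target_protein_ids, function(v) v[v %in% ids])
  rownames(view$ppis) <- rownames(view$bioactivities) <-
    rownames(view$predicted_dtis) <- NULL
  rebuild_indices(view)
}

#' Confidence filter for PPI edges
#'
#' Drops PPI edges below a confidence threshold, with separate thresholds
#' for cross-category pairs (by default: the two proteins have different
#' taxa, e.g. host-virus) and within-category pairs (same taxon, e.g.
#' host-host).
#'
#' @param ds a `kg_datastore`.
#' @param min_cross minimum confidence for cross-category edges, in
#'   \[0, 1\].
#' @param min_within minimum confidence for within-category edges.
#' @param cross_predicate `function(taxon_a, taxon_b) -> logical`,
#'   classifying each pair; default: different taxon is cross-category.
#' @return a filtered `kg_datastore` view with indices recomputed.
#' @export
filter_ppis_by_confidence <- function(ds, min_cross = 0.35, min_within = 0.6,
                                      cross_predicate = NULL) {
  stopifnot(inherits(ds, "kg_datastore"))
  stopifnot(min_cross >= 0, min_cross <= 1, min_within >= 0, min_within <= 1)
  if (is.null(cross_predicate))
    cross_predicate <- function(ta, tb) ta != tb
  tax <- stats::setNames(ds$proteins$taxon_id, ds$proteins$protein_id)
  is_cross <- mapply(cross_predicate,
                     tax[ds$ppis$protein_a], tax[ds$ppis$protein_b])
  if (nrow(ds$ppis) == 0L) is_cross <- logical(0)
  thr <- ifelse(is_cross, min_cross, min_within)
  keep <- ds$ppis$confidence >= thr
  view <- ds
  view$ppis <- ds$ppis[keep, , drop = FALSE]
  rownames(view$ppis) <- NULL
  rebuild_indices(view)
}
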