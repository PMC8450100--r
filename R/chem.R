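# Chem: bioactivity filtering, the iterative pChEMBL pool search,
# fingerprint similarity, compound clustering and diverse selection.

# Standard activity types giving roughly comparable half-maximal measures;
# matching is case-insensitive.
ALLOWED_STANDARD_TYPES <- c("IC50", "EC50", "AC50", "XC50", "Ki", "Kd",
                            "Potency")

#' Convert a half-maximal concentration to the pChEMBL scale
#'
#' pChEMBL is the negative base-10 logarithm of a molar half-maximal
#' activity value, so 10 uM corresponds to pChEMBL 5.
#'
#' @param value positive concentration value.
#' @param unit one of `"M"`, `"mM"`, `"uM"` (alias `"µM"`), `"nM"`.
#' @return the pChEMBL value `-log10(molar)`.
#' @examples
#' pchembl_from_concentration(10, "uM")  # 5
#' @export
pchembl_from_concentration <- function(value, unit = c("M", "mM", "uM", "µM", "nM")) {
  unit <- match.arg(unit)
  if (any(value <= 0)) stop_kg("concentration must be > 0")
  scale <- c(M = 1, mM = 1e-3, uM = 1e-6, nM = 1e-9)
  if (unit == "µM") unit <- "uM"
  -log10(value * scale[[unit]])
}

#' Tanimoto similarity of two fingerprints
#'
#' Fingerprints are sparse binary vectors given by their on-bit positions
#' (integer vectors); similarity is `|intersection| / |union|`.
#'
#' @param a,b integer vectors of on-bit positions; at least one must be
#'   non-empty.
#' @return similarity in \[0, 1\].
#' @export
tanimoto <- function(a, b) {
  if (length(a) == 0L && length(b) == 0L)
    stop_kg("tanimoto undefined for two empty fingerprints")
  i <- length(intersect(a, b))
  i / (length(a) + length(b) - i)
}

#' Cluster compounds on fingerprint similarity
#'
#' Default method is leader clustering: compounds are visited in a
#' canonical order (descending on-bit count, then lexicographic id); each
#' joins the first existing cluster whose representative (its founder) has
#' Tanimoto similarity `>= threshold`, otherwise it founds a new cluster.
#' The enforced contract is member-to-representative similarity
#' `>= threshold`; full within-cluster clique similarity is not guaranteed.
#' Because the visiting order is canonical, the assignment is invariant
#' under permutation of the input.
#'
#' `method = "single_linkage"` instead takes connected components of the
#' pairwise-similarity graph at the threshold (a sensitivity check; it
#' computes all pairwise similarities and is quadratic).
#'
#' @param fingerprints named list of integer on-bit vectors (names are
#'   compound ids).
#' @param threshold similarity cut-off in (0, 1\] (default 0.5: cluster
#'   members are at least 50% similar to their representative).
#' @param method `"leader"` (default) or `"single_linkage"`.
#' @return a `kg_clusters` object: list with `assignment` (named integer
#'   cluster ids per compound) and `representatives` (compound id per
#'   cluster).
#' @export
cluster_compounds <- function(fingerprints, threshold = 0.5,
                              method = c("leader", "single_linkage")) {
  method <- match.arg(method)
  stopifnot(threshold > 0, threshold <= 1)
  ids <- names(fingerprints)
  if (length(fingerprints) == 0L)
    return(structure(list(assignment = stats::setNames(integer(0), character(0)),
                          representatives = character(0),
                          threshold = threshold, method = method),
                     class = "kg_clusters"))
  if (is.null(ids) || any(!nzchar(ids)) || anyDuplicated(ids))
    stop_kg("fingerprints must be uniquely named by compound id")
  if (any(lengths(fingerprints) == 0L))
    stop_kg("empty fingerprint(s): %s",
            paste(ids[lengths(fingerprints) == 0L], collapse = ", "))
  ord <- order_radix(-lengths(fingerprints), ids)
  ids <- ids[ord]
  fps <- fingerprints[ord]

  if (method == "leader") {
    assignment <- integer(length(ids))
    rep_fps <- list()
    for (i in seq_along(ids)) {
      placed <- FALSE
      for (cl in seq_along(rep_fps)) {
        if (tanimoto(fps[[i]], rep_fps[[cl]]) >= threshold) {
          assignment[i] <- cl
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        rep_fps[[length(rep_fps) + 1L]] <- fps[[i]]
        names(rep_fps)[length(rep_fps)] <- ids[i]
        assignment[i] <- length(rep_fps)
      }
    }
    representatives <- names(rep_fps)
  } else {
    n <- length(ids)
    g <- igraph::make_empty_graph(n, directed = FALSE)
    if (n > 1L) {
      pairs <- utils::combn(n, 2L)
      sim <- apply(pairs, 2L, function(p) tanimoto(fps[[p[1L]]], fps[[p[2L]]]))
      keep <- sim >= threshold
      if (any(keep))
        g <- igraph::add_edges(g, as.vector(pairs[, keep, drop = FALSE]))
    }
    comp <- igraph::components(g)$membership
    # renumber components in first-visit order of the canonical ordering
    first <- !duplicated(comp)
    renum <- stats::setNames(seq_len(sum(first)), comp[first])
    assignment <- unname(renum[as.character(comp)])
    representatives <- ids[first][order(renum[as.character(comp[first])])]
  }
  structure(list(assignment = stats::setNames(assignment, ids),
                 representatives = representatives,
                 threshold = threshold, method = method),
            class = "kg_clusters")
}

#' @export
print.kg_clusters <- function(x, ...) {
  cat(sprintf("<kg_clusters> %d compound(s) in %d cluster(s) (%s, threshold %g)\n",
              length(x$assignment), length(x$representatives), x$method,
              x$threshold))
  invisible(x)
}

#' Filter bioactivity records for knowledge-graph use
#'
#' Keeps records whose target is a single protein, whose assay organism is
#' in `taxa`, whose standard type is one of the comparable half-maximal
#' types (IC50, EC50, AC50, XC50, Ki, Kd, Potency; case-insensitive), and
#' whose pChEMBL value is present and `>= pchembl_min`. Records without a
#' pChEMBL value are always dropped.
#'
#' @param records a bioactivities table (see [load_datastore()]).
#' @param taxa assay taxon ids to keep; `NULL` keeps all.
#' @param allowed_standard_types character vector of admissible standard
#'   types.
#' @param pchembl_min minimum pChEMBL value (`>= 0`).
#' @return the surviving rows of `records`.
#' @export
filter_bioactivities <- function(records, taxa = 9606L,
                                 allowed_standard_types = ALLOWED_STANDARD_TYPES,
                                 pchembl_min = 5) {
  stopifnot(pchembl_min >= 0)
  keep <- records$target_kind == "single_protein" &
    toupper(records$standard_type) %in% toupper(allowed_standard_types) &
    !is.na(records$pchembl) & records$pchembl >= pchembl_min
  if (!is.null(taxa)) keep <- keep & records$taxon_id %in% as.integer(taxa)
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assemble the candidate compound pool via the iterative pChEMBL cutoff
#'
#' Starting from a strict cutoff (default pChEMBL 8), counts the distinct
#' compounds with at least one filtered bioactivity against the target set.
#' If the first run returns fewer than `lower` compounds the cutoff is
#' lowered by `step` (never below `floor`, default 5 i.e. 10 uM) until at
#' least `lower` are gathered; if the first run returns more than `upper`
#' the cutoff is raised by `step` until the count drops to `upper` or
#' fewer. The direction is keyed on the first run, so the scan is
#' monotone; count monotonicity in the cutoff guarantees it finds a cutoff
#' inside `[lower, upper]` whenever one exists on the scanned grid.
#'
#' If the floor is reached while still short of `lower`, whatever remains
#' is accepted and `floor_relaxed` is set; likewise `max_iter` caps the
#' scan.
#'
#' @param ds a `kg_datastore`.
#' @param target_proteins accessions the compounds must be active against.
#' @param lower,upper pool size bounds (default 1000 and 2500 distinct
#'   compounds).
#' @param start_cutoff initial pChEMBL cutoff (default 8).
#' @param floor lowest admissible cutoff (default 5).
#' @param step cutoff increment per iteration (default 0.5).
#' @param max_iter maximum iterations (default 20).
#' @param taxa assay taxa passed to [filter_bioactivities()].
#' @return a `kg_compound_pool`: list with `records` (the filtered
#'   bioactivity rows at the final cutoff), `distinct_compounds`,
#'   `final_cutoff`, `iterations`, `floor_relaxed`, `max_iter_hit`.
#' @export
assemble_compound_pool <- function(ds, target_proteins,
                                   lower = 1000L, upper = 2500L,
                                   start_cutoff = 8, floor = 5, step = 0.5,
                                   max_iter = 20L, taxa = NULL) {
  stopifnot(inherits(ds, "kg_datastore"), floor <= start_cutoff, lower < upper)
  base <- filter_bioactivities(ds$bioactivities, taxa = taxa,
                               pchembl_min = floor)
  base <- base[base$target_protein_id %in% target_proteins, , drop = FALSE]
  pool_at <- function(cutoff) base[base$pchembl >= cutoff, , drop = FALSE]
  count_at <- function(cutoff) length(unique(pool_at(cutoff)$compound_id))

  mk <- function(cutoff, iterations, floor_relaxed = FALSE,
                 max_iter_hit = FALSE) {
    rec <- pool_at(cutoff)
    rec <- rec[order_radix(rec$compound_id, rec$target_protein_id,
                           -rec$pchembl), , drop = FALSE]
    rownames(rec) <- NULL
    structure(list(records = rec,
                   distinct_compounds = sort(unique(rec$compound_id)),
                   final_cutoff = cutoff, iterations = iterations,
                   floor_relaxed = floor_relaxed,
                   max_iter_hit = max_iter_hit),
              class = "kg_compound_pool")
  }

  if (length(target_proteins) == 0L || nrow(base) == 0L) {
    warn_kg("empty target set or no admissible bioactivities: empty pool")
    return(mk(start_cutoff, 0L, floor_relaxed = TRUE))
  }

  cutoff <- start_cutoff
  iter <- 1L
  n0 <- count_at(cutoff)
  if (n0 >= lower && n0 <= upper) return(mk(cutoff, iter))
  direction <- if (n0 < lower) -1 else +1
  repeat {
    if (iter >= max_iter)
      return(mk(cutoff, iter, max_iter_hit = TRUE))
    if (direction < 0 && cutoff <= floor)
      return(mk(floor, iter, floor_relaxed = TRUE))
    cutoff <- if (direction < 0) max(floor, cutoff - step) else cutoff + step
    iter <- iter + 1L
    n <- count_at(cutoff)
    if (direction < 0 && n >= lower) return(mk(cutoff, iter))
    if (direction > 0 && n <= upper) {
      return(mk(cutoff, iter, floor_relaxed = n < lower))
    }
  }
}

#' @export
print.kg_compound_pool <- function(x, ...) {
  cat(sprintf(paste0("<kg_compound_pool> %d distinct compound(s), %d record(s), ",
                     "final cutoff %.2f after %d iteration(s)%s%s\n"),
              length(x$distinct_compounds), nrow(x$records), x$final_cutoff,
              x$iterations,
              if (x$floor_relaxed) " [floor relaxed]" else "",
              if (x$max_iter_hit) " [max_iter hit]" else ""))
  invisible(x)
}

#' Cluster-aware diverse compound selection
#'
#' Walks an enrichment ranking of compounds best-first and keeps a
#' compound only if no compound of its cluster is already in the graph or
#' earlier in this selection; stops after `k` selections. This yields
#' structurally diverse ligands instead of stacks of same-scaffold
#' analogues with near-identical enrichment scores.
#'
#' @param ranked a `kg_enrichment` ranking whose `term_id` column holds
#'   compound ids.
#' @param clusters a `kg_clusters` assignment covering every ranked
#'   compound.
#' @param k maximum number of compounds to select.
#' @param already_present_clusters cluster ids already represented in the
#'   graph.
#' @return the selected rows of `ranked`, in selection order, with a
#'   `cluster` column appended.
#' @export
select_diverse_compounds <- function(ranked, clusters, k,
                                     already_present_clusters = integer(0)) {
  stopifnot(inherits(clusters, "kg_clusters"), k >= 0)
  if (nrow(ranked) > 0L && !all(ranked$term_id %in% names(clusters$assignment)))
    stop_kg("every ranked compound needs a cluster assignment")
  taken <- as.integer(already_present_clusters)
  sel <- integer(0)
  for (i in seq_len(nrow(ranked))) {
    if (length(sel) >= k) break
    cl <- clusters$assignment[[ranked$term_id[i]]]
    if (cl %in% taken) next
    taken <- c(taken, cl)
    sel <- c(sel, i)
  }
  out <- ranked[sel, , drop = FALSE]
  out$cluster <- unname(clusters$assignment[out$term_id])
  out
}
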