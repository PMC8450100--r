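# Enrichment: degree-weighted hypergeometric overrepresentation.
#
# Every node-filtering step in the builder ranks candidate terms by
#
#   E = (m^2 / n) / (M / N)
#
# where m is the number of graph proteins associated with the term, n the
# number of gene/protein nodes in the growing graph, M the number of
# datastore proteins associated with the term, and N the component total
# (distinct datastore proteins with at least one association in the term's
# component). Squaring m highlights the candidate with the higher graph
# degree among terms with otherwise similar scores, while the M/N
# denominator penalises promiscuous hub terms. The accompanying one-tailed
# significance S is the hypergeometric upper tail (one-tailed Fisher's
# exact test); it is reported, but never used as a selection criterion.

#' Enrichment score of a term for a growing graph
#'
#' Computes `E = (m^2 / n) / (M / N)`. Degenerate inputs (`n = 0` or
#' `M = 0`) yield 0: such a term is not enrichable. All arguments are
#' vectorized and recycled.
#'
#' @param m graph proteins associated with the term (`0 <= m <= min(n, M)`).
#' @param n gene/protein nodes in the graph.
#' @param M datastore proteins associated with the term.
#' @param N component total (> 0): datastore proteins with any association
#'   in the term's component.
#' @return numeric vector of scores, `>= 0`.
#' @examples
#' enrichment_score(3, 5, 4, 10)   # (9/5) / (4/10) = 4.5
#' @export
enrichment_score <- function(m, n, M, N) {
  if (any(N == 0)) stop_kg("empty component: N must be > 0")
  stopifnot(all(m >= 0), all(n >= 0), all(M >= 0), all(m <= pmin(n, M)),
            all(M <= N), all(n <= N))
  out <- rep(0, length(m + n + M + N))  # recycled length
  m <- rep_len(m, length(out)); n <- rep_len(n, length(out))
  M <- rep_len(M, length(out)); N <- rep_len(N, length(out))
  ok <- n > 0 & M > 0
  out[ok] <- (m[ok]^2 / n[ok]) / (M[ok] / N[ok])
  out
}

#' One-tailed hypergeometric significance of a term
#'
#' The upper-tail probability
#' `S = sum_{i=m}^{n} C(M, i) C(N-M, n-i) / C(N, n)`
#' (terms with `i > M` vanish under the convention `C(a, b) = 0` for
#' `b > a`), equivalently a one-tailed Fisher's exact test of
#' overrepresentation. Evaluated through the log-space hypergeometric tail
#' for numerical safety. Degenerate inputs (`n = 0` or `M = 0`) yield 1.
#'
#' @inheritParams enrichment_score
#' @return numeric vector of p-values in \[0, 1\].
#' @examples
#' enrichment_pvalue(3, 5, 4, 10)  # 66/252
#' @export
enrichment_pvalue <- function(m, n, M, N) {
  if (any(N == 0)) stop_kg("empty component: N must be > 0")
  stopifnot(all(m >= 0), all(n >= 0), all(M >= 0), all(m <= pmin(n, M)),
            all(M <= N), all(n <= N))
  p <- stats::phyper(m - 1, M, N - M, n, lower.tail = FALSE)
  pmin(pmax(p, 0), 1)
}

#' Rank a component's terms by enrichment against a protein set
#'
#' Scores every candidate term of an association index against the graph's
#' protein set and returns the ranking used for node filtering. Only terms
#' with `m >= 1` are candidates; `exclusions` (typically the query terms
#' themselves) are removed before ranking. Ties in E are broken by
#' ascending S, then descending m, then lexicographic term id, so the
#' ranking is fully deterministic.
#'
#' Graph proteins with no annotation at all in the component are excluded
#' from the draw (`n` counts graph proteins inside the component universe),
#' keeping the hypergeometric model well-defined (`n <= N`) on small
#' datastores. Since `n` is common to all terms this never changes the
#' ranking order.
#'
#' @param graph_proteins character vector of accession ids in the graph.
#' @param index term -> protein mapping, as from [build_annotation_index()].
#' @param N component total; defaults to `attr(index, "total")`.
#' @param exclusions term ids to omit from the ranking.
#' @return a `data.frame` (class `kg_enrichment`) with columns `term_id`,
#'   `m`, `n`, `M`, `N`, `E`, `S`, ordered best-first.
#' @export
rank_component_terms <- function(graph_proteins, index,
                                 N = attr(index, "total"),
                                 exclusions = character(0)) {
  if (is.null(N)) stop_kg("N not given and index carries no 'total' attribute")
  universe <- unique(unlist(index, use.names = FALSE))
  gp <- intersect(unique(graph_proteins), universe)
  n <- length(gp)
  idx <- index[setdiff(names(index), exclusions)]
  empty <- data.frame(term_id = character(0), m = integer(0), n = integer(0),
                      M = integer(0), N = integer(0), E = numeric(0),
                      S = numeric(0), stringsAsFactors = FALSE)
  class(empty) <- c("kg_enrichment", "data.frame")
  if (length(idx) == 0L || n == 0L) return(empty)
  m <- vapply(idx, function(p) sum(p %in% gp), 0L)
  keep <- m >= 1L
  if (!any(keep)) return(empty)
  m <- m[keep]
  M <- lengths(idx)[keep]
  out <- data.frame(term_id = names(idx)[keep], m = unname(m), n = n,
                    M = unname(M), N = N,
                    E = unname(enrichment_score(m, n, M, N)),
                    S = unname(enrichment_pvalue(m, n, M, N)),
                    stringsAsFactors = FALSE)
  out <- out[order_radix(-out$E, out$S, -out$m, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("kg_enrichment", "data.frame")
  out
}

#' Select the top-k admitted terms from a ranking
#'
#' Walks the ranking best-first and keeps the first `k` entries admitted by
#' `admit`. Significance is deliberately not a selection criterion: the
#' ranking order alone decides. The `admit` predicate receives the
#' candidate row and the data frame of entries already selected, enabling
#' stateful rules such as compound-cluster exclusion or ontology
#' parent-child thinning.
#'
#' @param ranked a ranking from [rank_component_terms()].
#' @param k maximum number of entries to keep (`>= 0`).
#' @param admit `function(candidate_row, selected_df) -> logical`, or `NULL`
#'   to admit everything.
#' @return the selected rows, in rank order (at most `k`).
#' @export
select_top_k <- function(ranked, k, admit = NULL) {
  stopifnot(k >= 0)
  if (k == 0L || nrow(ranked) == 0L) return(ranked[0, , drop = FALSE])
  if (is.null(admit)) return(ranked[seq_len(min(k, nrow(ranked))), , drop = FALSE])
  sel <- integer(0)
  for (i in seq_len(nrow(ranked))) {
    if (isTRUE(admit(ranked[i, , drop = FALSE], ranked[sel, , drop = FALSE])))
      sel <- c(sel, i)
    if (length(sel) >= k) break
  }
  ranked[sel, , drop = FALSE]
}

#' Admit predicate thinning close parent-child ontology terms
#'
#' Returns an admit predicate for [select_top_k()] that rejects a candidate
#' term whose direct parent or child (per the `parent_ids` column of the
#' terms table) has already been selected. Used to avoid stacking nearly
#' redundant phenotype terms from one ontology branch.
#'
#' @param terms the `terms` table of a datastore (needs `term_id`,
#'   `parent_ids`).
#' @return a `function(candidate, selected)` suitable for [select_top_k()].
#' @export
hpo_thinning_predicate <- function(terms) {
  parents <- stats::setNames(terms$parent_ids, terms$term_id)
  function(candidate, selected) {
    if (nrow(selected) == 0L) return(TRUE)
    cand <- candidate$term_id
    sel <- selected$term_id
    cand_parents <- parents[[cand]] %||% character(0)
    if (any(sel %in% cand_parents)) return(FALSE)
    sel_parents <- unlist(parents[sel], use.names = FALSE)
    !(cand %in% sel_parents)
  }
}
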