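# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Split a pipe-delimited multi-value TSV cell
#'
#' Collections store multi-valued fields (e.g. a protein's disease
#' annotations) as `|`-delimited strings inside one TSV cell. Empty cells and
#' NA map to `character(0)`.
#'
#' @param x character vector of cells.
#' @return list of character vectors, one per cell.
#' @keywords internal
#' @noRd
split_multi <- function(x) {
  if (length(x) == 0L) return(list())
  out <- strsplit(ifelse(is.na(x), "", x), "|", fixed = TRUE)
  lapply(out, function(v) v[nzchar(v)])
}

# Inverse of split_multi for serialization.
join_multi <- function(x) {
  vapply(x, paste, character(1), collapse = "|")
}

# Invert a (id -> set) relation given as parallel vectors: returns a named
# list keyed by `keys`, each element the sorted unique values associated.
invert_relation <- function(ids, keys) {
  stopifnot(length(ids) == length(keys))
  if (length(ids) == 0L) return(structure(list(), names = character(0)))
  sp <- split(ids, keys)
  lapply(sp, function(v) sort(unique(v)))
}

# Deterministic radix ordering for character tie-breaks, locale-independent.
order_radix <- function(...) order(..., method = "radix")

stop_kg <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warn_kg <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
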