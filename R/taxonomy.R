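#' Build a taxonomy index from a lineage table
#'
#' A taxonomy index maps every taxid to its parent taxid, rank and name and
#' supports ancestor-at-rank queries, which drive genus-to-strain direction
#' propagation. The structure is validated on construction: every parent must
#' resolve (or be a root) and the parent chain from every node must terminate
#' at a root without cycles. A node whose parent is itself is accepted as a
#' root only for the conventional NCBI root (taxid 1, or rank `"root"` /
#' `"no rank"`); any other self-parent is reported as a cycle.
#'
#' @param taxid Integer vector of taxon IDs (unique).
#' @param parent_taxid Integer vector of parent IDs; `NA` or `0` marks a root.
#' @param rank Character vector of rank names (`"genus"`, `"species"`, ...).
#' @param name Character vector of scientific names.
#' @return An object of class `taxonomy_index`.
#' @examples
#' tx <- taxonomy_index(
#'   taxid = c(1, 10, 100, 1000), parent_taxid = c(NA, 1, 10, 100),
#'   rank = c("root", "genus", "species", "strain"),
#'   name = c("root", "Faecalibacterium", "F. prausnitzii", "F. prausnitzii A2-165"))
#' ancestor_at_rank(tx, 1000, "genus")
#' @export
taxonomy_index <- function(taxid, parent_taxid, rank, name) {
  taxid <- as.integer(taxid)
  parent_taxid <- as.integer(parent_taxid)
  rank <- as.character(rank)
  name <- as.character(name)
  n <- length(taxid)
  stopifnot(length(parent_taxid) == n, length(rank) == n, length(name) == n)
  if (anyDuplicated(taxid)) {
    dup <- unique(taxid[duplicated(taxid)])
    stop_taxonomy(sprintf("duplicate taxids: %s", paste(dup, collapse = ", ")))
  }

  key <- as.character(taxid)
  is_root <- is.na(parent_taxid) | parent_taxid == 0L |
    (parent_taxid == taxid & (taxid == 1L | rank %in% c("root", "no rank")))
  parent_taxid[is_root] <- NA_integer_

  # orphan parents: referenced but not defined
  refd <- !is.na(parent_taxid)
  orphan <- setdiff(unique(parent_taxid[refd]), taxid)
  if (length(orphan) > 0L) {
    stop_taxonomy(sprintf("orphan parent taxids (referenced but undefined): %s",
                          paste(sort(orphan), collapse = ", ")))
  }

  parent <- stats::setNames(parent_taxid, key)
  # cycle check: walk each node to a root; a chain longer than n nodes or a
  # revisit means a cycle (includes non-root self-parents).
  state <- stats::setNames(integer(n), key) # 0 unseen, 1 on ok chain
  for (k in key) {
    chain <- character()
    cur <- k
    while (!is.na(cur)) {
      if (state[[cur]] == 1L) break
      if (cur %in% chain) {
        stop_taxonomy(sprintf("cycle detected in lineage involving taxid %s", cur))
      }
      chain <- c(chain, cur)
      p <- parent[[cur]]
      cur <- if (is.na(p)) NA_character_ else as.character(p)
    }
    state[chain] <- 1L
  }

  structure(
    list(parent = parent,
         rank = stats::setNames(rank, key),
         name = stats::setNames(name, key)),
    class = "taxonomy_index")
}

stop_taxonomy <- function(msg) {
  stop(errorCondition(msg, class = c("micrometab_taxonomy_error", "micrometab_error")))
}

#' @export
print.taxonomy_index <- function(x, ...) {
  cat(sprintf("<taxonomy_index: %d taxa, %d roots>\n",
              length(x$parent), sum(is.na(x$parent))))
  invisible(x)
}

#' @export
length.taxonomy_index <- function(x) length(x$parent)

#' Taxonomy lookups
#'
#' `tax_parent()`, `tax_rank()` and `tax_name()` look up single-node fields;
#' `tax_exists()` tests membership. All are vectorized over `taxid` and
#' return `NA` for unknown taxids.
#'
#' @param index A [taxonomy_index()].
#' @param taxid Integer vector of taxon IDs.
#' @return Parent taxids (integer), ranks or names (character), or logical.
#' @export
tax_parent <- function(index, taxid) {
  unname(index$parent[as.character(taxid)])
}

#' @rdname tax_parent
#' @export
tax_rank <- function(index, taxid) {
  unname(index$rank[as.character(taxid)])
}

#' @rdname tax_parent
#' @export
tax_name <- function(index, taxid) {
  unname(index$name[as.character(taxid)])
}

#' @rdname tax_parent
#' @export
tax_exists <- function(index, taxid) {
  as.character(taxid) %in% names(index$parent)
}

#' Find the ancestor of a taxon at a given rank
#'
#' Walks the parent chain starting at the node itself (so a genus-rank taxid
#' is its own genus ancestor) and returns the first node whose rank matches.
#'
#' @param index A [taxonomy_index()].
#' @param taxid Integer vector of query taxids.
#' @param rank Single rank name, e.g. `"genus"`.
#' @return Integer vector of ancestor taxids; `NA` where no ancestor of that
#'   rank exists or the query taxid is unknown.
#' @export
ancestor_at_rank <- function(index, taxid, rank) {
  vapply(as.integer(taxid), function(t) {
    cur <- as.character(t)
    if (!cur %in% names(index$parent)) return(NA_integer_)
    while (TRUE) {
      if (identical(unname(index$rank[[cur]]), rank)) return(as.integer(cur))
      p <- index$parent[[cur]]
      if (is.na(p)) return(NA_integer_)
      cur <- as.character(p)
    }
  }, integer(1))
}

#' Convert a taxonomy index back to a lineage tibble
#'
#' @param index A [taxonomy_index()].
#' @return A tibble with columns `taxid`, `parent_taxid`, `rank`, `name`.
#' @export
as_lineage_table <- function(index) {
  tibble::tibble(
    taxid = as.integer(names(index$parent)),
    parent_taxid = unname(index$parent),
    rank = unname(index$rank),
    name = unname(index$name))
}
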