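#' Harmonize association tables before scoring
#'
#' Curated association tables aggregate multiple literature sources, so the
#' same link is often recorded more than once and a disease-microbe pair may
#' be reported with opposite directions by different studies.
#' [deduplicate()] collapses exact duplicates on the association key;
#' [remove_contradictions()] drops every disease-microbe pair reported with
#' both directions (both records removed, not arbitrated -- a conservative
#' rule that keeps the table internally consistent).
#' [harmonize_disease_microbe()] runs both in order.
#'
#' Output rows are sorted by association key so downstream ranking is
#' reproducible, and both operations are idempotent and order-invariant.
#'
#' @name harmonize
NULL

new_harmonization_report <- function(records_in, records_out, duplicates_removed,
                                     contradictory_pairs) {
  structure(
    list(records_in = records_in,
         records_out = records_out,
         duplicates_removed = duplicates_removed,
         contradictory_pairs_removed = contradictory_pairs),
    class = "harmonization_report")
}

#' @export
print.harmonization_report <- function(x, ...) {
  cat("Harmonization report\n")
  cat(sprintf("  records in:            %d\n", x$records_in))
  cat(sprintf("  duplicates removed:    %d\n", x$duplicates_removed))
  cat(sprintf("  contradictory pairs:   %d (both directions dropped)\n",
              nrow(x$contradictory_pairs_removed)))
  cat(sprintf("  records out:           %d\n", x$records_out))
  invisible(x)
}

empty_pairs <- function() {
  tibble::tibble(disease_id = character(), microbe_taxid = integer())
}

#' Collapse duplicate association records
#'
#' The association key is `(disease_id, microbe_taxid, direction)` for
#' disease-microbe records and `(microbe_taxid, metabolite_id)` for
#' production links (detected from the columns present). The first
#' occurrence's evidence fields (PMID, method, names) are kept.
#'
#' @param records A disease-microbe or microbe-metabolite tibble.
#' @return A list with elements `records` (key-sorted, duplicate-free) and
#'   `report` (a `harmonization_report`).
#' @export
deduplicate <- function(records) {
  key_cols <- if ("metabolite_id" %in% names(records)) {
    c("microbe_taxid", "metabolite_id")
  } else {
    c("disease_id", "microbe_taxid", "direction")
  }
  n_in <- nrow(records)
  out <- dplyr::distinct(records, dplyr::across(dplyr::all_of(key_cols)),
                         .keep_all = TRUE)
  out <- dplyr::arrange(out, dplyr::across(dplyr::all_of(key_cols)))
  list(records = out,
       report = new_harmonization_report(n_in, nrow(out), n_in - nrow(out),
                                         empty_pairs()))
}

#' Remove contradictory disease-microbe direction pairs
#'
#' Every `(disease_id, microbe_taxid)` pair recorded with both `increase`
#' and `decrease` is removed entirely; the dropped pairs are listed in the
#' report so the rule can be audited. A contradiction under one disease does
#' not affect the same microbe under another disease.
#'
#' @param records A deduplicated disease-microbe tibble.
#' @return A list with elements `records` and `report`.
#' @export
remove_contradictions <- function(records) {
  n_in <- nrow(records)
  conflicts <- records |>
    dplyr::distinct(.data$disease_id, .data$microbe_taxid, .data$direction) |>
    dplyr::count(.data$disease_id, .data$microbe_taxid) |>
    dplyr::filter(.data$n > 1L) |>
    dplyr::select("disease_id", "microbe_taxid") |>
    dplyr::arrange(.data$disease_id, .data$microbe_taxid)
  out <- dplyr::anti_join(records, conflicts,
                          by = c("disease_id", "microbe_taxid"))
  out <- dplyr::arrange(out, .data$disease_id, .data$microbe_taxid, .data$direction)
  list(records = out,
       report = new_harmonization_report(n_in, nrow(out), 0L, conflicts))
}

#' @rdname harmonize
#' @param records A raw disease-microbe tibble.
#' @return `harmonize_disease_microbe()`: a list with `records` and a
#'   combined `report`.
#' @export
harmonize_disease_microbe <- function(records) {
  d <- deduplicate(records)
  c_ <- remove_contradictions(d$records)
  list(records = c_$records,
       report = new_harmonization_report(
         records_in = d$report$records_in,
         records_out = c_$report$records_out,
         duplicates_removed = d$report$duplicates_removed,
         contradictory_pairs = c_$report$contradictory_pairs_removed))
}
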