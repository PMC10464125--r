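#' Genus-to-strain direction propagation
#'
#' Disease-microbe associations are curated at the genus level (the
#' resolution of 16S and most metagenomic surveys), while metabolite
#' production links are recorded for strains. The propagation rule assumes
#' that when a genus increases or decreases in a disease, every strain of
#' that genus carries the same direction. Propagation is restricted to the
#' *strain universe* -- the distinct microbe taxids of the harmonized
#' microbe-metabolite table -- because only metabolite-producing strains can
#' contribute to the association counts.
#'
#' @name propagate
NULL

#' Strains of a genus within a strain universe
#'
#' Returns every member of `strain_universe` whose genus-rank ancestor is
#' `genus_taxid`. Universe members whose own rank is species or subspecies
#' are treated as strain-level members; their genus ancestor decides
#' membership. If `genus_taxid` is not itself genus-rank, a warning is
#' emitted and its own genus-rank ancestor is used for the query.
#'
#' @param taxonomy A [taxonomy_index()].
#' @param genus_taxid A single taxid expected to have rank `"genus"`.
#' @param strain_universe Integer vector of candidate member taxids.
#' @return Integer vector (subset of `strain_universe`), sorted.
#' @export
strains_of_genus <- function(taxonomy, genus_taxid, strain_universe) {
  genus_taxid <- as.integer(genus_taxid)
  if (!tax_exists(taxonomy, genus_taxid)) {
    stop_taxonomy(sprintf("taxid %d not found in taxonomy", genus_taxid))
  }
  if (!identical(tax_rank(taxonomy, genus_taxid), "genus")) {
    warning(sprintf("taxid %d has rank '%s', not genus; using its genus-rank ancestor",
                    genus_taxid, tax_rank(taxonomy, genus_taxid)),
            call. = FALSE)
    genus_taxid <- ancestor_at_rank(taxonomy, genus_taxid, "genus")
    if (is.na(genus_taxid)) {
      stop_taxonomy("no genus-rank ancestor found for the queried taxid")
    }
  }
  universe <- unique(as.integer(strain_universe))
  anc <- ancestor_at_rank(taxonomy, universe, "genus")
  sort(universe[!is.na(anc) & anc == genus_taxid])
}

#' Propagate genus-level directions to a strain panel
#'
#' For each disease, the increased (decreased) strain set is the union over
#' its increased (decreased) genera of [strains_of_genus()] members; a
#' strain reachable from two same-direction genera is counted once.
#' Contradiction removal upstream guarantees the two sets are disjoint.
#' Genera absent from the taxonomy are reported in the `skipped` attribute
#' and skipped rather than fatal (curation tables routinely carry retired
#' taxids); diseases whose genera expand to no universe strains are listed
#' in the `empty_diseases` attribute.
#'
#' @param assocs Harmonized (contradiction-free) disease-microbe tibble.
#' @param taxonomy A [taxonomy_index()].
#' @param strain_universe Integer vector, normally the distinct
#'   `microbe_taxid`s of the harmonized microbe-metabolite table.
#' @return A `strain_panel` tibble with columns `disease_id`,
#'   `strain_taxid`, `direction`, `source_genus_taxid`, sorted by disease,
#'   direction, strain.
#' @export
propagate_directions <- function(assocs, taxonomy, strain_universe) {
  strain_universe <- unique(as.integer(strain_universe))
  genus_anc <- ancestor_at_rank(taxonomy, strain_universe, "genus")

  skipped <- tibble::tibble(disease_id = character(), microbe_taxid = integer(),
                            reason = character())
  rows <- vector("list", nrow(assocs))
  for (i in seq_len(nrow(assocs))) {
    g <- assocs$microbe_taxid[[i]]
    if (!tax_exists(taxonomy, g)) {
      skipped <- dplyr::bind_rows(skipped, tibble::tibble(
        disease_id = assocs$disease_id[[i]], microbe_taxid = g,
        reason = "taxid not in taxonomy"))
      next
    }
    gq <- g
    if (!identical(tax_rank(taxonomy, g), "genus")) {
      gq <- ancestor_at_rank(taxonomy, g, "genus")
      if (is.na(gq)) {
        skipped <- dplyr::bind_rows(skipped, tibble::tibble(
          disease_id = assocs$disease_id[[i]], microbe_taxid = g,
          reason = "no genus-rank ancestor"))
        next
      }
    }
    members <- strain_universe[!is.na(genus_anc) & genus_anc == gq]
    if (length(members) == 0L) next
    rows[[i]] <- tibble::tibble(
      disease_id = assocs$disease_id[[i]],
      strain_taxid = members,
      direction = assocs$direction[[i]],
      source_genus_taxid = g)
  }
  panel <- dplyr::bind_rows(rows)
  if (nrow(panel) == 0L) {
    panel <- tibble::tibble(disease_id = character(), strain_taxid = integer(),
                            direction = character(), source_genus_taxid = integer())
  }
  # one row per (disease, strain, direction); keep smallest source genus
  panel <- panel |>
    dplyr::arrange(.data$disease_id, .data$direction, .data$strain_taxid,
                   .data$source_genus_taxid) |>
    dplyr::distinct(.data$disease_id, .data$strain_taxid, .data$direction,
                    .keep_all = TRUE) |>
    dplyr::arrange(.data$disease_id, .data$direction, .data$strain_taxid)

  empty <- setdiff(unique(assocs$disease_id), unique(panel$disease_id))
  attr(panel, "skipped") <- skipped
  attr(panel, "empty_diseases") <- sort(empty)
  class(panel) <- c("strain_panel", class(panel))
  panel
}

#' Per-disease increased/decreased strain totals of a panel
#'
#' @param panel A strain panel from [propagate_directions()].
#' @return A tibble with columns `disease_id`, `M` (increased strains) and
#'   `N` (decreased strains).
#' @export
panel_totals <- function(panel) {
  tibble::as_tibble(panel) |>
    dplyr::count(.data$disease_id, .data$direction) |>
    tidyr::pivot_wider(names_from = "direction", values_from = "n",
                       values_fill = 0L) |>
    (\(d) {
      if (!"increase" %in% names(d)) d$increase <- 0L
      if (!"decrease" %in% names(d)) d$decrease <- 0L
      d
    })() |>
    dplyr::transmute(.data$disease_id, M = .data$increase, N = .data$decrease)
}
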