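#' Association strength and confidence scores
#'
#' For a disease with `M` increased and `N` decreased strains, and a
#' metabolite produced by `m` of the increased and `n` of the decreased
#' strains, the association strength score is
#'
#' \deqn{S_{as} = m/M - n/N}
#'
#' and the confidence score is
#'
#' \deqn{S_{ac} = (m+n)\,|S_{as}|.}
#'
#' A positive score ties the metabolite to disease-enriched microbes
#' (marker-like); a negative score ties it to disease-depleted microbes
#' (drug-like). When a disease has strains in only one direction (`M = 0` or
#' `N = 0`) the missing class's ratio contributes 0, which keeps the formula
#' total and makes single-direction diseases score exactly +1 or -1 for
#' metabolites their strains produce.
#'
#' @param m,n Producers among increased / decreased strains.
#' @param M,N Increased / decreased strain totals for the disease.
#' @param s_as An association strength score.
#' @return `association_strength()`: scores in `[-1, 1]`;
#'   `confidence()`: non-negative scores bounded by `m + n`.
#' @examples
#' association_strength(m = 0, M = 7, n = 5, N = 8)  # -0.625
#' confidence(m = 0, n = 5, s_as = -0.625)           # 3.125
#' @export
association_strength <- function(m, M, n, N) {
  stopifnot(all(m >= 0), all(n >= 0), all(m <= M | M == 0), all(n <= N | N == 0))
  term_inc <- ifelse(M > 0, m / M, 0)
  term_dec <- ifelse(N > 0, n / N, 0)
  term_inc - term_dec
}

#' @rdname association_strength
#' @export
confidence <- function(m, n, s_as) {
  (m + n) * abs(s_as)
}

#' Meaningfulness thresholds
#'
#' An association is *meaningful* when `|S_as|` exceeds `s_as_abs_min` and
#' `S_ac` exceeds `s_ac_min`; both comparisons are strict, so boundary
#' values fail.
#'
#' @param s_as_abs_min Minimum absolute association strength (default 0.05).
#' @param s_ac_min Minimum confidence (default 1).
#' @return A `thresholds` list.
#' @export
meaning_thresholds <- function(s_as_abs_min = 0.05, s_ac_min = 1) {
  stopifnot(s_as_abs_min >= 0, s_ac_min >= 0)
  structure(list(s_as_abs_min = s_as_abs_min, s_ac_min = s_ac_min),
            class = "thresholds")
}

#' Tally producer counts for every disease-metabolite pair
#'
#' Per disease, `M`/`N` are the sizes of the increased/decreased strain
#' sets; per (disease, metabolite), `m`/`n` count the increased/decreased
#' strains producing that metabolite. Pairs with `m + n = 0` are not
#' emitted: their confidence is 0, they can never pass the strict
#' thresholds, and emitting them would grow output quadratically.
#'
#' @param panel A strain panel from [propagate_directions()].
#' @param links Harmonized microbe-metabolite tibble.
#' @return A tibble with columns `disease_id`, `metabolite_id`, `m`, `n`,
#'   `M`, `N`.
#' @export
tally_counts <- function(panel, links) {
  totals <- panel_totals(panel)
  produced <- dplyr::inner_join(
    tibble::as_tibble(panel),
    dplyr::distinct(links, .data$microbe_taxid, .data$metabolite_id),
    by = c(strain_taxid = "microbe_taxid"),
    relationship = "many-to-many")
  if (nrow(produced) == 0L) {
    return(tibble::tibble(disease_id = character(), metabolite_id = integer(),
                          m = integer(), n = integer(), M = integer(), N = integer()))
  }
  produced |>
    dplyr::count(.data$disease_id, .data$metabolite_id, .data$direction) |>
    tidyr::pivot_wider(names_from = "direction", values_from = "n",
                       values_fill = 0L) |>
    (\(d) {
      if (!"increase" %in% names(d)) d$increase <- 0L
      if (!"decrease" %in% names(d)) d$decrease <- 0L
      d
    })() |>
    dplyr::transmute(.data$disease_id, .data$metabolite_id,
                     m = .data$increase, n = .data$decrease) |>
    dplyr::inner_join(totals, by = "disease_id") |>
    dplyr::arrange(.data$disease_id, .data$metabolite_id)
}

#' Classify scored associations against thresholds
#'
#' Adds/overwrites the `meaningful` flag (strict comparisons) and the
#' `label` column: `marker_like` for positive scores, `drug_like` for
#' negative, `neutral` for exactly zero.
#'
#' @param scored A tibble with columns `s_as`, `s_ac`.
#' @param thresholds A [meaning_thresholds()] list.
#' @return The input tibble with `meaningful` and `label` columns.
#' @export
classify <- function(scored, thresholds = meaning_thresholds()) {
  scored$meaningful <- abs(scored$s_as) > thresholds$s_as_abs_min &
    scored$s_ac > thresholds$s_ac_min
  scored$label <- dplyr::case_when(
    scored$s_as > 0 ~ "marker_like",
    scored$s_as < 0 ~ "drug_like",
    .default = "neutral")
  scored
}

#' Score every disease-metabolite pair end to end
#'
#' Runs the full pipeline: harmonize both tables, build the strain universe
#' from the harmonized production links, propagate genus directions to
#' strains, tally counts, score and classify. Output is sorted per disease
#' by ascending `s_as` (most drug-like first), ties broken by descending
#' `s_ac` then ascending `metabolite_id`, so "k-th strongest negative
#' association" is well defined.
#'
#' @param disease_microbe Raw disease-microbe tibble
#'   (see [read_disease_microbe_table()]).
#' @param microbe_metabolite Raw microbe-metabolite tibble.
#' @param taxonomy A [taxonomy_index()].
#' @param thresholds A [meaning_thresholds()] list.
#' @param meaningful_only Keep only meaningful associations.
#' @return A scored-association tibble (`disease_id`, `metabolite_id`, `m`,
#'   `n`, `M`, `N`, `s_as`, `s_ac`, `meaningful`, `label`) with
#'   `harmonization`, `skipped` and `empty_diseases` attributes.
#' @export
score_all <- function(disease_microbe, microbe_metabolite, taxonomy,
                      thresholds = meaning_thresholds(),
                      meaningful_only = FALSE) {
  dm <- harmonize_disease_microbe(disease_microbe)
  mm <- deduplicate(microbe_metabolite)
  universe <- unique(mm$records$microbe_taxid)
  panel <- propagate_directions(dm$records, taxonomy, universe)
  if (nrow(panel) == 0L) {
    warning("no disease expanded to any universe strain; output is empty",
            call. = FALSE)
  }
  counts <- tally_counts(panel, mm$records)
  counts$s_as <- association_strength(counts$m, counts$M, counts$n, counts$N)
  counts$s_ac <- confidence(counts$m, counts$n, counts$s_as)
  scored <- classify(counts, thresholds)
  if (meaningful_only) scored <- dplyr::filter(scored, .data$meaningful)
  scored <- dplyr::arrange(scored, .data$disease_id, .data$s_as,
                           dplyr::desc(.data$s_ac), .data$metabolite_id)
  attr(scored, "harmonization") <- list(disease_microbe = dm$report,
                                        microbe_metabolite = mm$report)
  attr(scored, "skipped") <- attr(panel, "skipped")
  attr(scored, "empty_diseases") <- attr(panel, "empty_diseases")
  scored
}

#' Summarize scored associations per disease
#'
#' The per-disease mean association strength over all emitted pairs, sorted
#' in decreasing order of the mean (ties broken by disease id) -- the order
#' used to compare diseases by the overall direction of their metabolite
#' associations.
#'
#' @param scored A scored-association tibble.
#' @return A tibble with columns `disease_id`, `mean_s_as`, `n_metabolites`.
#' @export
summarize_by_disease <- function(scored) {
  tibble::as_tibble(scored) |>
    dplyr::summarise(mean_s_as = mean(.data$s_as),
                     n_metabolites = dplyr::n(),
                     .by = "disease_id") |>
    dplyr::arrange(dplyr::desc(.data$mean_s_as), .data$disease_id)
}
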