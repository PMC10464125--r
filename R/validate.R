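#' Direction-consistency validation against experimental labels
#'
#' Compares the sign of each predicted association strength score with an
#' experimentally observed direction of the metabolite in the disease. A
#' labeled pair is `not_scored` when it is absent from the scored output or
#' not meaningful; otherwise it is `consistent` when the observed direction
#' is `up` and `S_as > 0`, or `down` and `S_as < 0`, and `inconsistent`
#' otherwise (a score of exactly 0 is inconsistent with either direction).
#' The consistency fraction is computed over meaningful-scored pairs only --
#' the method does not claim to score every experimental pair, only that the
#' pairs it does call meaningful point the right way.
#'
#' @param scored A scored-association tibble from [score_all()].
#' @param labels A validation tibble (`disease_id`, `metabolite_id`,
#'   `observed_direction` in `up`/`down`), e.g. from
#'   [read_validation_table()].
#' @return A `validation_report`: list with `pairs` (one row per label:
#'   `disease_id`, `metabolite_id`, `s_as`, `meaningful`,
#'   `observed_direction`, `status`), `n_experimental`,
#'   `n_scored_meaningful`, `n_consistent`, `consistency_fraction` (`NA`
#'   when nothing was scored meaningful) and `consistency_percent` (one
#'   decimal, round half away from zero).
#' @export
compare_directions <- function(scored, labels) {
  stopifnot(all(c("disease_id", "metabolite_id", "observed_direction") %in% names(labels)))
  conflicts <- labels |>
    dplyr::distinct(.data$disease_id, .data$metabolite_id, .data$observed_direction) |>
    dplyr::count(.data$disease_id, .data$metabolite_id) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(conflicts) > 0L) {
    stop_format(sprintf(
      "conflicting observed directions for %d labeled pair(s), e.g. (%s, %s)",
      nrow(conflicts), conflicts$disease_id[[1]], conflicts$metabolite_id[[1]]))
  }
  labels <- dplyr::distinct(labels, .data$disease_id, .data$metabolite_id,
                            .keep_all = TRUE)

  pairs <- labels |>
    dplyr::select("disease_id", "metabolite_id", "observed_direction") |>
    dplyr::left_join(
      tibble::as_tibble(scored)[, c("disease_id", "metabolite_id", "s_as", "meaningful")],
      by = c("disease_id", "metabolite_id"))
  pairs$meaningful[is.na(pairs$meaningful)] <- FALSE
  pairs$status <- ifelse(
    !pairs$meaningful, "not_scored",
    ifelse((pairs$observed_direction == "up" & pairs$s_as > 0) |
             (pairs$observed_direction == "down" & pairs$s_as < 0),
           "consistent", "inconsistent"))
  pairs <- pairs[, c("disease_id", "metabolite_id", "s_as", "meaningful",
                     "observed_direction", "status")]

  n_meaningful <- sum(pairs$status != "not_scored")
  n_consistent <- sum(pairs$status == "consistent")
  frac <- if (n_meaningful > 0L) n_consistent / n_meaningful else NA_real_
  structure(
    list(pairs = pairs,
         n_experimental = nrow(pairs),
         n_scored_meaningful = n_meaningful,
         n_consistent = n_consistent,
         consistency_fraction = frac,
         consistency_percent = if (is.na(frac)) NA_real_ else round_half_away(100 * frac, 1)),
    class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("Direction-consistency validation\n")
  cat(sprintf("  experimental pairs:  %d\n", x$n_experimental))
  cat(sprintf("  scored meaningful:   %d\n", x$n_scored_meaningful))
  cat(sprintf("  sign-consistent:     %d\n", x$n_consistent))
  if (is.na(x$consistency_fraction)) {
    cat("  consistency:         undefined (no labeled pair scored meaningful)\n")
  } else {
    cat(sprintf("  consistency:         %.1f%%\n", x$consistency_percent))
  }
  invisible(x)
}
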