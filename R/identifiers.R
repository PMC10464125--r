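#' Validate and normalize an identifier in one of the three namespaces
#'
#' Diseases are named by MeSH descriptors (a letter followed by digits, e.g.
#' `D003424`), microbes by NCBI Taxonomy IDs and metabolites by PubChem CIDs
#' (both positive integers). Raw tokens from curation tables are normalized
#' (case, whitespace, integer parse); anything malformed is an error that
#' names the namespace and the offending value -- dirty identifiers are never
#' silently dropped.
#'
#' @param raw Character or numeric vector of raw identifier tokens.
#' @param namespace One of `"MESH"`, `"TAXID"`, `"CID"`.
#' @return For `MESH`, an uppercase character vector; for `TAXID`/`CID`, a
#'   positive integer vector.
#' @examples
#' validate_identifier("d003424", "MESH")
#' validate_identifier("853", "TAXID")
#' @export
validate_identifier <- function(raw, namespace = c("MESH", "TAXID", "CID")) {
  namespace <- match.arg(namespace)
  raw_chr <- trimws(as.character(raw))
  if (length(raw_chr) == 0L) return(if (namespace == "MESH") character() else integer())
  bad_empty <- is.na(raw_chr) | raw_chr == ""
  if (any(bad_empty)) {
    stop_identifier(namespace, raw_chr[bad_empty][1L], "empty identifier")
  }
  if (namespace == "MESH") {
    out <- toupper(raw_chr)
    ok <- grepl("^[A-Z][0-9]+$", out)
    if (!all(ok)) {
      stop_identifier(namespace, raw_chr[!ok][1L],
                      "expected a letter followed by digits")
    }
    return(out)
  }
  # TAXID / CID: strictly digits, positive
  ok <- grepl("^[0-9]+$", raw_chr)
  if (!all(ok)) {
    stop_identifier(namespace, raw_chr[!ok][1L], "expected a positive integer")
  }
  out <- suppressWarnings(as.integer(raw_chr))
  bad <- is.na(out) | out <= 0L
  if (any(bad)) {
    stop_identifier(namespace, raw_chr[bad][1L], "expected a positive integer")
  }
  out
}

stop_identifier <- function(namespace, value, why) {
  stop(errorCondition(
    sprintf("invalid %s identifier %s: %s", namespace, dQuote(value, q = FALSE), why),
    namespace = namespace, value = value,
    class = c("micrometab_identifier_error", "micrometab_error")
  ))
}

# Map a direction token (case-insensitive) onto "increase"/"decrease".
# Returns NA_character_ for unknown tokens; callers report row numbers.
normalize_direction <- function(tokens) {
  x <- tolower(trimws(as.character(tokens)))
  out <- rep(NA_character_, length(x))
  out[x %in% c("increase", "increased", "up")] <- "increase"
  out[x %in% c("decrease", "decreased", "down")] <- "decrease"
  out
}

#' Round half away from zero
#'
#' Scores are printed with a fixed number of decimals using round-half-away
#' (so a confidence score of 3.125 prints as 3.13, not the IEEE half-even
#' 3.12 that [round()] would give).
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Numeric vector rounded half away from zero.
#' @examples
#' round_half_away(3.125, 2) # 3.13
#' @export
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

format_score <- function(x, digits) {
  sprintf(paste0("%.", digits, "f"), round_half_away(x, digits))
}
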