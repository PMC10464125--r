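#' Table readers and writers
#'
#' The package defines four canonical UTF-8 tab-separated formats, each with
#' a header row:
#'
#' * `disease_microbe.tsv`: `disease_id`, `disease_name`, `microbe_taxid`,
#'   `microbe_name`, `direction`, `pmid`, `method` (the last four optional).
#' * `microbe_metabolite.tsv`: `microbe_taxid`, `microbe_name` (optional),
#'   `metabolite_id`, `metabolite_name` (optional).
#' * `lineage.tsv`: `taxid`, `parent_taxid`, `rank`, `name`; alternatively
#'   the NCBI taxdump dialect (`nodes.dmp` + `names.dmp`).
#' * `validation.tsv`: `disease_id`, `metabolite_id`, `observed_direction`,
#'   `pmid` (optional).
#'
#' A `column_map` (named character vector, canonical name -> file column
#' name) lets any reader consume files with different headers. Every data row
#' yields exactly one record or one located error; files with any malformed
#' row are rejected with a message listing every offending line, because
#' silent loss from dirty curation tables is worse than failure.
#'
#' @name table-io
NULL

read_tsv_quiet <- function(path) {
  if (!file.exists(path)) {
    stop_format(sprintf("file not found: %s", path))
  }
  readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                  progress = FALSE, na = c("", "NA"))
}

stop_format <- function(msg) {
  stop(errorCondition(msg, class = c("micrometab_format_error", "micrometab_error")))
}

# Rename file columns to canonical names via column_map and check presence.
apply_column_map <- function(df, column_map, required, optional = character()) {
  if (!is.null(column_map)) {
    for (canon in names(column_map)) {
      have <- column_map[[canon]]
      if (have %in% names(df)) names(df)[names(df) == have] <- canon
    }
  }
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop_format(sprintf("missing required column(s): %s",
                        paste(missing, collapse = ", ")))
  }
  for (opt in optional) if (!opt %in% names(df)) df[[opt]] <- NA_character_
  df[, c(required, optional), drop = FALSE]
}

# Collects per-row errors; each message carries the 1-based file line number
# (header is line 1, first data row is line 2).
row_errors <- function() {
  msgs <- character()
  list(add = function(row, what) {
    msgs <<- c(msgs, sprintf("line %d: %s", row + 1L, what))
  },
  raise = function(path) {
    if (length(msgs) > 0L) {
      stop_format(sprintf("%d malformed row(s) in %s:\n  %s",
                          length(msgs), path, paste(msgs, collapse = "\n  ")))
    }
  })
}

# Parse a column of positive-integer identifiers, registering row errors.
parse_id_column <- function(x, namespace, colname, errs) {
  out <- rep(NA_integer_, length(x))
  for (i in seq_along(x)) {
    v <- tryCatch(validate_identifier(x[[i]], namespace), error = function(e) NULL)
    if (is.null(v)) {
      errs$add(i, sprintf("invalid %s %s in column '%s'",
                          namespace, dQuote(x[[i]], q = FALSE), colname))
    } else out[[i]] <- v
  }
  out
}

parse_optional_pmid <- function(x) {
  suppressWarnings(as.integer(x))
}

#' Read a disease-microbe association table
#'
#' Direction tokens `increase`/`increased`/`up` and
#' `decrease`/`decreased`/`down` are mapped case-insensitively onto the
#' `increase`/`decrease` enum; any other token is a row-level error.
#'
#' @param path Path to a tab-separated file with a header row.
#' @param column_map Optional named character vector mapping canonical column
#'   names (`disease_id`, `microbe_taxid`, `direction`, ...) to the file's
#'   column names.
#' @return A tibble with columns `disease_id`, `microbe_taxid`, `direction`,
#'   `disease_name`, `microbe_name`, `pmid`, `method`.
#' @export
read_disease_microbe_table <- function(path, column_map = NULL) {
  df <- read_tsv_quiet(path)
  df <- apply_column_map(df, column_map,
                         required = c("disease_id", "microbe_taxid", "direction"),
                         optional = c("disease_name", "microbe_name", "pmid", "method"))
  errs <- row_errors()
  n <- nrow(df)
  disease_id <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    v <- tryCatch(validate_identifier(df$disease_id[[i]], "MESH"),
                  error = function(e) NULL)
    if (is.null(v)) errs$add(i, sprintf("invalid MESH id %s", dQuote(df$disease_id[[i]], q = FALSE)))
    else disease_id[[i]] <- v
  }
  taxid <- parse_id_column(df$microbe_taxid, "TAXID", "microbe_taxid", errs)
  direction <- normalize_direction(df$direction)
  for (i in which(is.na(direction))) {
    errs$add(i, sprintf("unknown direction token %s", dQuote(df$direction[[i]], q = FALSE)))
  }
  errs$raise(path)
  tibble::tibble(
    disease_id = disease_id,
    microbe_taxid = taxid,
    direction = direction,
    disease_name = df$disease_name,
    microbe_name = df$microbe_name,
    pmid = parse_optional_pmid(df$pmid),
    method = df$method)
}

#' Read a microbe-metabolite production table
#'
#' Production links are presence-only (no direction); duplicate
#' (taxid, metabolite) rows are kept at read time and removed by
#' [deduplicate()].
#'
#' @inheritParams read_disease_microbe_table
#' @return A tibble with columns `microbe_taxid`, `metabolite_id`,
#'   `microbe_name`, `metabolite_name`.
#' @export
read_microbe_metabolite_table <- function(path, column_map = NULL) {
  df <- read_tsv_quiet(path)
  df <- apply_column_map(df, column_map,
                         required = c("microbe_taxid", "metabolite_id"),
                         optional = c("microbe_name", "metabolite_name"))
  errs <- row_errors()
  taxid <- parse_id_column(df$microbe_taxid, "TAXID", "microbe_taxid", errs)
  cid <- parse_id_column(df$metabolite_id, "CID", "metabolite_id", errs)
  errs$raise(path)
  tibble::tibble(
    microbe_taxid = taxid,
    metabolite_id = cid,
    microbe_name = df$microbe_name,
    metabolite_name = df$metabolite_name)
}

#' Read an experimental validation table
#'
#' @inheritParams read_disease_microbe_table
#' @return A tibble with columns `disease_id`, `metabolite_id`,
#'   `observed_direction` (`"up"`/`"down"`), `pmid`.
#' @export
read_validation_table <- function(path, column_map = NULL) {
  df <- read_tsv_quiet(path)
  df <- apply_column_map(df, column_map,
                         required = c("disease_id", "metabolite_id", "observed_direction"),
                         optional = "pmid")
  errs <- row_errors()
  n <- nrow(df)
  disease_id <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    v <- tryCatch(validate_identifier(df$disease_id[[i]], "MESH"),
                  error = function(e) NULL)
    if (is.null(v)) errs$add(i, sprintf("invalid MESH id %s", dQuote(df$disease_id[[i]], q = FALSE)))
    else disease_id[[i]] <- v
  }
  cid <- parse_id_column(df$metabolite_id, "CID", "metabolite_id", errs)
  dir <- normalize_direction(df$observed_direction)
  for (i in which(is.na(dir))) {
    errs$add(i, sprintf("unknown direction token %s",
                        dQuote(df$observed_direction[[i]], q = FALSE)))
  }
  errs$raise(path)
  tibble::tibble(
    disease_id = disease_id,
    metabolite_id = cid,
    observed_direction = ifelse(dir == "increase", "up", "down"),
    pmid = parse_optional_pmid(df$pmid))
}

#' Read a taxonomy lineage, in either of two dialects
#'
#' `"simple"` expects a TSV with columns `taxid`, `parent_taxid`, `rank`,
#' `name`. `"taxdump"` expects the NCBI taxdump pair `nodes.dmp` /
#' `names.dmp` (pipe-with-tab delimited; only `scientific name` rows of
#' `names.dmp` are used): pass the directory containing both files, or the
#' path to `nodes.dmp`.
#'
#' @param path File (simple TSV or nodes.dmp) or directory (taxdump).
#' @param dialect `"simple"` or `"taxdump"`.
#' @return A [taxonomy_index()].
#' @export
read_lineage <- function(path, dialect = c("simple", "taxdump")) {
  dialect <- match.arg(dialect)
  if (dialect == "simple") {
    df <- read_tsv_quiet(path)
    df <- apply_column_map(df, NULL,
                           required = c("taxid", "parent_taxid", "rank", "name"))
    errs <- row_errors()
    taxid <- parse_id_column(df$taxid, "TAXID", "taxid", errs)
    errs$raise(path)
    parent <- suppressWarnings(as.integer(df$parent_taxid))
    return(taxonomy_index(taxid, parent, df$rank, df$name))
  }
  # taxdump dialect
  if (dir.exists(path)) {
    nodes_path <- file.path(path, "nodes.dmp")
    names_path <- file.path(path, "names.dmp")
  } else {
    nodes_path <- path
    names_path <- file.path(dirname(path), "names.dmp")
  }
  if (!file.exists(nodes_path)) stop_format(sprintf("file not found: %s", nodes_path))
  if (!file.exists(names_path)) stop_format(sprintf("file not found: %s", names_path))
  nodes <- parse_dmp(nodes_path)
  taxid <- as.integer(vapply(nodes, `[[`, "", 1L))
  parent <- as.integer(vapply(nodes, `[[`, "", 2L))
  rank <- vapply(nodes, `[[`, "", 3L)
  nm <- parse_dmp(names_path)
  nm_class <- vapply(nm, function(f) if (length(f) >= 4L) f[[4L]] else "", "")
  nm <- nm[nm_class == "scientific name"]
  name_map <- stats::setNames(vapply(nm, `[[`, "", 2L), vapply(nm, `[[`, "", 1L))
  name <- unname(name_map[as.character(taxid)])
  name[is.na(name)] <- as.character(taxid)[is.na(name)]
  taxonomy_index(taxid, parent, rank, name)
}

# Split NCBI .dmp lines on the "\t|\t" (and trailing "\t|") delimiters.
parse_dmp <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  lapply(lines, function(l) {
    l <- sub("\t\\|$", "", l)
    trimws(strsplit(l, "\t\\|\t?")[[1]])
  })
}

#' Write a lineage index to the simple TSV dialect
#'
#' @param index A [taxonomy_index()].
#' @param path Output path.
#' @export
write_lineage <- function(index, path) {
  readr::write_tsv(as_lineage_table(index), path, progress = FALSE)
  invisible(path)
}

#' Write (and re-read) a scored association table
#'
#' Columns: `disease_id`, `metabolite_id`, `m`, `n`, `M`, `N`, `s_as`,
#' `s_ac`, `meaningful`, `label`. `s_as` is printed to 3 decimals and `s_ac`
#' to 2, rounding half away from zero (so 3.125 prints as `3.13`). With
#' `full_precision = TRUE` two extra columns `s_as_full`, `s_ac_full` carry
#' the unrounded values.
#'
#' @param scored A scored-association tibble from [score_all()].
#' @param path Output path.
#' @param full_precision Also write full-precision score columns.
#' @export
write_scored_table <- function(scored, path, full_precision = FALSE) {
  out <- tibble::tibble(
    disease_id = scored$disease_id,
    metabolite_id = scored$metabolite_id,
    m = scored$m, n = scored$n, M = scored$M, N = scored$N,
    s_as = format_score(scored$s_as, 3),
    s_ac = format_score(scored$s_ac, 2),
    meaningful = scored$meaningful,
    label = scored$label)
  if (full_precision) {
    out$s_as_full <- scored$s_as
    out$s_ac_full <- scored$s_ac
  }
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_scored_table
#' @export
read_scored_table <- function(path) {
  df <- read_tsv_quiet(path)
  required <- c("disease_id", "metabolite_id", "m", "n", "M", "N",
                "s_as", "s_ac", "meaningful", "label")
  df <- apply_column_map(df, NULL, required,
                         optional = c("s_as_full", "s_ac_full"))
  tibble::tibble(
    disease_id = df$disease_id,
    metabolite_id = as.integer(df$metabolite_id),
    m = as.integer(df$m), n = as.integer(df$n),
    M = as.integer(df$M), N = as.integer(df$N),
    s_as = if (all(!is.na(df$s_as_full))) as.numeric(df$s_as_full) else as.numeric(df$s_as),
    s_ac = if (all(!is.na(df$s_ac_full))) as.numeric(df$s_ac_full) else as.numeric(df$s_ac),
    meaningful = as.logical(df$meaningful),
    label = df$label)
}
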