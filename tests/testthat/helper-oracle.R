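# Independent brute-force re-implementation of the whole scoring pipeline,
# written with plain base-R loops over a lineage data frame. Used only as an
# oracle; shares no code with the package internals.

oracle_genus_of <- function(lineage, taxid) {
  rank <- setNames(lineage$rank, lineage$taxid)
  parent <- setNames(lineage$parent_taxid, lineage$taxid)
  cur <- as.character(taxid)
  repeat {
    if (!cur %in% names(rank)) return(NA_integer_)
    if (rank[[cur]] == "genus") return(as.integer(cur))
    p <- parent[[cur]]
    if (is.na(p)) return(NA_integer_)
    cur <- as.character(p)
  }
}

oracle_score_all <- function(dm, mm, lineage) {
  dm <- as.data.frame(dm)
  mm <- as.data.frame(mm)

  # deduplicate
  dm <- dm[!duplicated(dm[, c("disease_id", "microbe_taxid", "direction")]), ]
  mm <- mm[!duplicated(mm[, c("microbe_taxid", "metabolite_id")]), ]

  # remove contradictions by full pairwise scan
  drop <- rep(FALSE, nrow(dm))
  for (i in seq_len(nrow(dm))) {
    for (j in seq_len(nrow(dm))) {
      if (i != j &&
          dm$disease_id[i] == dm$disease_id[j] &&
          dm$microbe_taxid[i] == dm$microbe_taxid[j] &&
          dm$direction[i] != dm$direction[j]) {
        drop[i] <- TRUE
      }
    }
  }
  dm <- dm[!drop, ]

  universe <- unique(mm$microbe_taxid)
  genus_of <- vapply(universe, function(t) oracle_genus_of(lineage, t), integer(1))

  diseases <- sort(unique(dm$disease_id))
  metabolites <- sort(unique(mm$metabolite_id))
  out <- list()
  for (d in diseases) {
    inc <- integer(); dec <- integer()
    for (k in seq_along(universe)) {
      g <- genus_of[k]
      if (is.na(g)) next
      hit <- dm$disease_id == d & dm$microbe_taxid == g
      if (any(hit & dm$direction == "increase")) inc <- c(inc, universe[k])
      if (any(hit & dm$direction == "decrease")) dec <- c(dec, universe[k])
    }
    M <- length(inc); N <- length(dec)
    for (cid in metabolites) {
      producers <- mm$microbe_taxid[mm$metabolite_id == cid]
      m <- length(intersect(inc, producers))
      n <- length(intersect(dec, producers))
      if (m + n == 0L) next
      s_as <- (if (M > 0) m / M else 0) - (if (N > 0) n / N else 0)
      s_ac <- (m + n) * abs(s_as)
      out[[length(out) + 1L]] <- data.frame(
        disease_id = d, metabolite_id = cid, m = m, n = n, M = M, N = N,
        s_as = s_as, s_ac = s_ac,
        meaningful = abs(s_as) > 0.05 && s_ac > 1,
        label = if (s_as > 0) "marker_like" else if (s_as < 0) "drug_like" else "neutral")
    }
  }
  if (length(out) == 0L) {
    return(data.frame(disease_id = character(), metabolite_id = integer(),
                      m = integer(), n = integer(), M = integer(), N = integer(),
                      s_as = numeric(), s_ac = numeric(),
                      meaningful = logical(), label = character()))
  }
  res <- do.call(rbind, out)
  res[order(res$disease_id, res$s_as, -res$s_ac, res$metabolite_id), ]
}
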