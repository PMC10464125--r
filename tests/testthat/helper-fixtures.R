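# Shared in-code fixtures: a small ranked taxonomy and matching tables.

# root(1) -> genera 10 (Faecalibacterium-like, 2 strains), 20 (3 strains),
# 30 (no universe strains); species node 201 interposed under genus 20.
fixture_lineage <- function() {
  tibble::tibble(
    taxid = c(1L, 10L, 20L, 30L, 101L, 102L, 201L, 2011L, 2012L, 2013L),
    parent_taxid = c(NA, 1L, 1L, 1L, 10L, 10L, 20L, 201L, 201L, 201L),
    rank = c("root", "genus", "genus", "genus", "strain", "strain",
             "species", "strain", "strain", "strain"),
    name = c("root", "genus_A", "genus_B", "genus_C", "A s1", "A s2",
             "B sp", "B s1", "B s2", "B s3"))
}

fixture_taxonomy <- function() {
  l <- fixture_lineage()
  taxonomy_index(l$taxid, l$parent_taxid, l$rank, l$name)
}

fixture_dm <- function() {
  tibble::tibble(
    disease_id = c("D000001", "D000001", "D000002"),
    microbe_taxid = c(10L, 20L, 10L),
    direction = c("decrease", "increase", "increase"),
    disease_name = NA_character_, microbe_name = NA_character_,
    pmid = NA_integer_, method = NA_character_)
}

fixture_mm <- function() {
  tibble::tibble(
    microbe_taxid = c(101L, 102L, 2011L, 2012L, 2013L, 101L),
    metabolite_id = c(7001L, 7001L, 7002L, 7002L, 7001L, 7003L),
    microbe_name = NA_character_, metabolite_name = NA_character_)
}

# Tables realizing a disease panel with M increased / N decreased strains and
# one metabolite produced by m increased and n decreased strains; used to
# rebuild the worked T2DM-style examples end to end.
fixture_counts_tables <- function(m, M, n, N, disease = "D000099", cid = 5001L) {
  inc_genus <- 900L; dec_genus <- 901L
  inc_strains <- if (M > 0) 9100L + seq_len(M) else integer()
  dec_strains <- if (N > 0) 9200L + seq_len(N) else integer()
  lineage <- tibble::tibble(
    taxid = c(1L, inc_genus, dec_genus, inc_strains, dec_strains),
    parent_taxid = c(NA_integer_, 1L, 1L,
                     rep(inc_genus, M), rep(dec_genus, N)),
    rank = c("root", "genus", "genus", rep("strain", M + N)),
    name = as.character(c("root", "inc", "dec", inc_strains, dec_strains)))
  dm <- tibble::tibble(
    disease_id = disease,
    microbe_taxid = c(if (M > 0) inc_genus, if (N > 0) dec_genus),
    direction = c(if (M > 0) "increase", if (N > 0) "decrease"),
    disease_name = NA_character_, microbe_name = NA_character_,
    pmid = NA_integer_, method = NA_character_)
  producers <- c(head(inc_strains, m), head(dec_strains, n))
  mm <- tibble::tibble(
    microbe_taxid = c(inc_strains, dec_strains, producers),
    metabolite_id = c(rep(4999L, M + N), rep(cid, length(producers))),
    microbe_name = NA_character_, metabolite_name = NA_character_)
  list(dm = dm, mm = mm, lineage = lineage,
       taxonomy = taxonomy_index(lineage$taxid, lineage$parent_taxid,
                                 lineage$rank, lineage$name),
       disease = disease, cid = cid)
}

write_fixture_tsv <- function(df, dir = withr::local_tempdir(.local_envir = parent.frame()),
                              name = "table.tsv") {
  path <- file.path(dir, name)
  readr::write_tsv(df, path, progress = FALSE)
  path
}
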