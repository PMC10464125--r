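test_that("strains_of_genus returns exactly the universe members under the genus", {
  tx <- fixture_taxonomy()
  universe <- c(101L, 102L, 2011L, 2012L, 2013L)
  # genus with two member strains (Faecalibacterium-style)
  expect_identical(strains_of_genus(tx, 10L, universe), c(101L, 102L))
  # strains under a different genus are excluded; species node interposed
  expect_identical(strains_of_genus(tx, 20L, universe), c(2011L, 2012L, 2013L))
  # genus with no universe members
  expect_identical(strains_of_genus(tx, 30L, universe), integer())
  # universe restriction
  expect_identical(strains_of_genus(tx, 10L, c(101L, 2011L)), 101L)
  # absent genus is a resolution error
  expect_error(strains_of_genus(tx, 777L, universe),
               class = "micrometab_taxonomy_error")
})

test_that("non-genus query taxid warns and resolves through its genus ancestor", {
  tx <- fixture_taxonomy()
  universe <- c(101L, 102L, 2011L, 2012L, 2013L)
  expect_warning(res <- strains_of_genus(tx, 201L, universe), "not genus")
  expect_identical(res, c(2011L, 2012L, 2013L))
})

test_that("propagation expands genus directions over the universe", {
  tx <- fixture_taxonomy()
  universe <- c(101L, 102L, 2011L, 2012L, 2013L)
  panel <- propagate_directions(fixture_dm(), tx, universe)

  d1 <- panel[panel$disease_id == "D000001", ]
  expect_identical(d1$strain_taxid[d1$direction == "decrease"], c(101L, 102L))
  expect_identical(d1$strain_taxid[d1$direction == "increase"],
                   c(2011L, 2012L, 2013L))
  expect_identical(unique(d1$source_genus_taxid[d1$direction == "decrease"]), 10L)

  d2 <- panel[panel$disease_id == "D000002", ]
  expect_identical(d2$strain_taxid, c(101L, 102L))
  expect_identical(unique(d2$direction), "increase")

  totals <- panel_totals(panel)
  expect_equal(totals$M[totals$disease_id == "D000001"], 3L)
  expect_equal(totals$N[totals$disease_id == "D000001"], 2L)
  expect_equal(totals$N[totals$disease_id == "D000002"], 0L)
})

test_that("same-direction multi-genus reach counts a strain once; sets stay disjoint", {
  tx <- fixture_taxonomy()
  dm <- tibble::tibble(
    disease_id = "D000009",
    microbe_taxid = c(10L, 20L),
    direction = "increase",
    disease_name = NA_character_, microbe_name = NA_character_,
    pmid = NA_integer_, method = NA_character_)
  panel <- propagate_directions(dm, tx, c(101L, 102L, 2011L, 2012L, 2013L))
  expect_equal(nrow(panel), 5L)  # 2 + 3 disjoint union
  expect_false(any(duplicated(panel[, c("disease_id", "strain_taxid")])))
})

test_that("unresolvable genera are skipped with a report; empty diseases flagged", {
  tx <- fixture_taxonomy()
  dm <- tibble::tibble(
    disease_id = c("D000001", "D000007", "D000008"),
    microbe_taxid = c(10L, 424242L, 30L),  # retired taxid; genus w/o strains
    direction = "increase",
    disease_name = NA_character_, microbe_name = NA_character_,
    pmid = NA_integer_, method = NA_character_)
  panel <- propagate_directions(dm, tx, c(101L, 102L))
  skipped <- attr(panel, "skipped")
  expect_equal(nrow(skipped), 1L)
  expect_identical(skipped$microbe_taxid, 424242L)
  expect_identical(attr(panel, "empty_diseases"), c("D000007", "D000008"))
  expect_identical(unique(panel$disease_id), "D000001")
})

test_that("panel equals a brute-force per-strain ancestor scan on synthetic bundles", {
  for (seed in c(11L, 12L, 13L)) {
    b <- generate_dataset(sim_config(n_diseases = 3, n_genera = 5,
                                     strains_per_genus = c(2, 3),
                                     n_metabolites = 10, seed = seed))
    dm <- harmonize_disease_microbe(b$disease_microbe)$records
    universe <- unique(b$microbe_metabolite$microbe_taxid)
    panel <- propagate_directions(dm, b$taxonomy, universe)

    # oracle: for each strain x disease, look up the genus direction directly
    expected <- list()
    for (s in sort(universe)) {
      g <- oracle_genus_of(b$lineage, s)
      hits <- dm[dm$microbe_taxid == g, ]
      for (i in seq_len(nrow(hits))) {
        expected[[length(expected) + 1L]] <-
          data.frame(disease_id = hits$disease_id[i], strain_taxid = s,
                     direction = hits$direction[i])
      }
    }
    expected <- do.call(rbind, expected)
    expected <- expected[order(expected$disease_id, expected$direction,
                               expected$strain_taxid), ]
    expect_equal(as.data.frame(panel[, c("disease_id", "strain_taxid", "direction")]),
                 expected, ignore_attr = TRUE)

    # universe monotonicity: dropping a strain never adds panel rows
    sub <- setdiff(universe, universe[1])
    panel_sub <- propagate_directions(dm, b$taxonomy, sub)
    key <- function(p) paste(p$disease_id, p$strain_taxid, p$direction)
    expect_true(all(key(panel_sub) %in% key(panel)))
    # per-disease sets are bounded by the universe and disjoint
    totals <- panel_totals(panel)
    expect_true(all(totals$M + totals$N <= length(universe)))
    expect_false(any(duplicated(panel[, c("disease_id", "strain_taxid")])))
  }
})
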