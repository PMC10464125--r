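test_that("association strength and confidence reproduce the worked values", {
  # metabolite produced by 0 of 7 increased and 5 of 8 decreased strains
  s <- association_strength(m = 0, M = 7, n = 5, N = 8)
  expect_identical(s, -0.625)
  expect_identical(confidence(m = 0, n = 5, s_as = s), 3.125)
  # 4 of 8 decreased producers
  s2 <- association_strength(m = 0, M = 7, n = 4, N = 8)
  expect_identical(s2, -0.5)
  expect_identical(confidence(0, 4, s2), 2)
  # balanced ratios cancel
  expect_identical(association_strength(2, 4, 1, 2), 0)
  # single-direction disease: zero-denominator term contributes 0
  expect_identical(association_strength(1, 1, 0, 0), 1)
  expect_identical(association_strength(0, 0, 3, 3), -1)
})

test_that("classification thresholds are strict at the boundary", {
  base <- tibble::tibble(s_as = c(-0.625, 0.05, -0.2, 0.3, 0),
                         s_ac = c(3.125, 5, 1.0, 1.2, 0))
  cl <- classify(base, meaning_thresholds())
  expect_identical(cl$meaningful, c(TRUE, FALSE, FALSE, TRUE, FALSE))
  expect_identical(cl$label, c("drug_like", "marker_like", "drug_like",
                               "marker_like", "neutral"))
})

test_that("tally_counts reproduces hand-built counts and suppresses m+n=0 pairs", {
  fx <- fixture_counts_tables(m = 0, M = 7, n = 5, N = 8)
  dm <- harmonize_disease_microbe(fx$dm)$records
  mm <- deduplicate(fx$mm)$records
  panel <- propagate_directions(dm, fx$taxonomy, unique(mm$microbe_taxid))
  counts <- tally_counts(panel, mm)
  row <- counts[counts$metabolite_id == fx$cid, ]
  expect_equal(unname(unlist(row[, c("m", "n", "M", "N")])), c(0L, 5L, 7L, 8L))

  # a metabolite produced by no panel strain is absent
  mm2 <- dplyr::bind_rows(mm, tibble::tibble(
    microbe_taxid = 4L, metabolite_id = 6000L,
    microbe_name = NA_character_, metabolite_name = NA_character_))
  counts2 <- tally_counts(panel, mm2)
  expect_false(6000L %in% counts2$metabolite_id)
  expect_true(all(counts2$m + counts2$n >= 1L))
})

test_that("score_all orders per disease so k-th strongest negative is defined", {
  fx <- fixture_counts_tables(m = 0, M = 7, n = 5, N = 8)
  scored <- score_all(fx$dm, fx$mm, fx$taxonomy)
  expect_identical(scored$metabolite_id, c(fx$cid, 4999L))
  expect_equal(scored$s_as, c(-0.625, 0))
  expect_identical(scored$label, c("drug_like", "neutral"))
  expect_identical(scored$meaningful, c(TRUE, FALSE))

  # determinism: scoring twice gives identical output
  again <- score_all(fx$dm, fx$mm, fx$taxonomy)
  expect_identical(as.data.frame(scored), as.data.frame(again))

  # meaningful_only filters
  only <- score_all(fx$dm, fx$mm, fx$taxonomy, meaningful_only = TRUE)
  expect_identical(only$metabolite_id, fx$cid)
})

test_that("empty production table gives empty output with a warning", {
  fx <- fixture_counts_tables(m = 0, M = 2, n = 1, N = 2)
  expect_warning(scored <- score_all(fx$dm, fx$mm[0, ], fx$taxonomy),
                 "empty")
  expect_equal(nrow(scored), 0L)
})

test_that("range, symmetry and exclusivity-extreme invariants hold", {
  set.seed(123)
  Ms <- sample(0:10, 1000, replace = TRUE)
  Ns <- sample(0:10, 1000, replace = TRUE)
  ms <- vapply(Ms, function(M) sample(0:M, 1), integer(1))
  ns <- vapply(Ns, function(N) sample(0:N, 1), integer(1))
  s <- association_strength(ms, Ms, ns, Ns)
  ac <- confidence(ms, ns, s)
  expect_true(all(s >= -1 & s <= 1))
  expect_true(all(ac >= 0 & ac <= ms + ns))
  # swapping the increase/decrease roles negates s_as, preserves s_ac
  s_swap <- association_strength(ns, Ns, ms, Ms)
  expect_equal(s_swap, -s, tolerance = 1e-15)
  expect_equal(confidence(ns, ms, s_swap), ac, tolerance = 1e-15)
  # exclusivity extremes
  expect_identical(association_strength(5, 5, 0, 8), 1)
  expect_identical(association_strength(0, 5, 8, 8), -1)
})

test_that("panel direction swap negates every score end to end", {
  b <- generate_dataset(sim_config(seed = 31L))
  scored <- score_all(b$disease_microbe, b$microbe_metabolite, b$taxonomy)
  dm_swapped <- b$disease_microbe
  dm_swapped$direction <- ifelse(dm_swapped$direction == "increase",
                                 "decrease", "increase")
  swapped <- score_all(dm_swapped, b$microbe_metabolite, b$taxonomy)
  key <- function(x) paste(x$disease_id, x$metabolite_id)
  expect_setequal(key(scored), key(swapped))
  merged <- merge(as.data.frame(scored), as.data.frame(swapped),
                  by = c("disease_id", "metabolite_id"))
  expect_equal(merged$s_as.y, -merged$s_as.x, tolerance = 1e-15)
  expect_equal(merged$s_ac.y, merged$s_ac.x, tolerance = 1e-15)
})

test_that("per-disease summaries are means in decreasing order", {
  scored <- tibble::tibble(
    disease_id = c("D2", "D2", "D1", "D1", "D3"),
    metabolite_id = 1:5, m = 1L, n = 1L, M = 2L, N = 2L,
    s_as = c(0.5, -0.5, 0.3, 0.1, -0.1),
    s_ac = 1, meaningful = TRUE, label = "x")
  sm <- summarize_by_disease(scored)
  expect_identical(sm$disease_id, c("D1", "D2", "D3"))
  expect_equal(sm$mean_s_as, c(0.2, 0, -0.1))
  expect_identical(sm$n_metabolites, c(2L, 2L, 1L))

  # fixture means equal an independent recomputation
  b <- generate_dataset(sim_config(seed = 19L))
  scored <- score_all(b$disease_microbe, b$microbe_metabolite, b$taxonomy)
  sm <- summarize_by_disease(scored)
  indep <- tapply(scored$s_as, scored$disease_id, mean)
  expect_equal(sm$mean_s_as, as.vector(indep[sm$disease_id]), tolerance = 1e-15)
  expect_true(all(diff(sm$mean_s_as) <= 0))
})
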