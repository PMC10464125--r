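#' Configuration for the synthetic data generator
#'
#' The generator emulates the structure of the two curated association
#' tables plus the lineage and validation tables: a three-level taxonomy
#' (root / genera / strains), directed disease-genus associations, random
#' presence-only strain-metabolite production links, and *planted* signal
#' metabolites produced exclusively by the decreased (drug-like) or
#' increased (marker-like) strains of a designated disease, so every stage
#' of the pipeline can be tested against known ground truth without any
#' download.
#'
#' @param n_diseases Number of diseases.
#' @param n_genera Number of genera under the root.
#' @param strains_per_genus Strains per genus: a single count or a
#'   `c(min, max)` range sampled per genus.
#' @param n_metabolites Number of background metabolites (planted
#'   metabolites are additional to none of these -- they are taken from the
#'   tail of this pool).
#' @param p_increase Probability an associated disease-genus pair has
#'   direction `increase` (otherwise `decrease`).
#' @param density_assoc Probability a (disease, genus) pair is associated.
#' @param density_prod Probability a background (strain, metabolite)
#'   production link exists.
#' @param n_planted_drug_like,n_planted_marker_like Planted metabolites
#'   produced exclusively by all decreased / increased strains of the
#'   designated disease.
#' @param label_noise Probability a generated validation label flips
#'   direction.
#' @param seed Integer seed; identical configurations and seeds give
#'   byte-identical bundles.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_diseases = 5, n_genera = 10, strains_per_genus = 3,
                       n_metabolites = 50, p_increase = 0.5,
                       density_assoc = 0.5, density_prod = 0.1,
                       n_planted_drug_like = 1, n_planted_marker_like = 1,
                       label_noise = 0, seed = 1) {
  probs <- c(p_increase = p_increase, density_assoc = density_assoc,
             density_prod = density_prod, label_noise = label_noise)
  if (any(probs < 0 | probs > 1)) stop("probabilities must be in [0, 1]")
  stopifnot(n_diseases >= 1, n_genera >= 1, all(strains_per_genus >= 1),
            n_metabolites >= 0, n_planted_drug_like >= 0,
            n_planted_marker_like >= 0,
            n_planted_drug_like + n_planted_marker_like <= n_metabolites)
  structure(list(
    n_diseases = as.integer(n_diseases), n_genera = as.integer(n_genera),
    strains_per_genus = as.integer(strains_per_genus),
    n_metabolites = as.integer(n_metabolites),
    p_increase = p_increase, density_assoc = density_assoc,
    density_prod = density_prod,
    n_planted_drug_like = as.integer(n_planted_drug_like),
    n_planted_marker_like = as.integer(n_planted_marker_like),
    label_noise = label_noise, seed = as.integer(seed)),
    class = "sim_config")
}

# Independent sub-stream per table so e.g. adding metabolites does not
# perturb the taxonomy draw. Offsets are arbitrary fixed primes.
sub_seed <- function(cfg, offset) (cfg$seed %% 1000000000L) + offset

#' Generate a synthetic input bundle with known ground truth
#'
#' @param cfg A [sim_config()].
#' @param dir Optional output directory; when given, the four canonical
#'   TSVs plus `ground_truth.tsv` are written there.
#' @return A list with tibbles `disease_microbe`, `microbe_metabolite`,
#'   `lineage`, `validation`, `ground_truth`, a `taxonomy` index, and the
#'   `config`.
#' @export
generate_dataset <- function(cfg, dir = NULL) {
  stopifnot(inherits(cfg, "sim_config"))

  # --- taxonomy ---------------------------------------------------------
  set.seed(sub_seed(cfg, 11L))
  genus_taxids <- 1000L + seq_len(cfg$n_genera)
  n_strains <- if (length(cfg$strains_per_genus) == 2L) {
    sample(cfg$strains_per_genus[1]:cfg$strains_per_genus[2],
           cfg$n_genera, replace = TRUE)
  } else rep(cfg$strains_per_genus[1], cfg$n_genera)
  strain_rows <- do.call(rbind, lapply(seq_len(cfg$n_genera), function(i) {
    if (n_strains[i] == 0L) return(NULL)
    data.frame(taxid = 100000L + genus_taxids[i] %% 100000L * 100L + seq_len(n_strains[i]),
               parent_taxid = genus_taxids[i],
               rank = "strain",
               name = sprintf("genus_%d strain %d", i, seq_len(n_strains[i])))
  }))
  lineage <- tibble::as_tibble(rbind(
    data.frame(taxid = 1L, parent_taxid = NA_integer_, rank = "root", name = "root"),
    data.frame(taxid = genus_taxids, parent_taxid = 1L, rank = "genus",
               name = sprintf("genus_%d", seq_len(cfg$n_genera))),
    strain_rows))
  taxonomy <- taxonomy_index(lineage$taxid, lineage$parent_taxid,
                             lineage$rank, lineage$name)

  diseases <- sprintf("D%06d", seq_len(cfg$n_diseases))

  # --- disease-genus associations --------------------------------------
  set.seed(sub_seed(cfg, 23L))
  grid <- expand.grid(disease_id = diseases, genus = genus_taxids,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[order(grid$disease_id, grid$genus), ]
  keep <- stats::runif(nrow(grid)) < cfg$density_assoc
  dirs <- ifelse(stats::runif(nrow(grid)) < cfg$p_increase, "increase", "decrease")
  dm <- tibble::tibble(
    disease_id = grid$disease_id[keep],
    microbe_taxid = grid$genus[keep],
    direction = dirs[keep],
    disease_name = sub("^D0*", "disease_", grid$disease_id[keep]),
    microbe_name = tax_name(taxonomy, grid$genus[keep]),
    pmid = NA_integer_,
    method = "synthetic")

  strain_of_genus <- split(strain_rows$taxid, strain_rows$parent_taxid)
  panel_strains <- function(disease, direction) {
    g <- dm$microbe_taxid[dm$disease_id == disease & dm$direction == direction]
    sort(unique(unlist(strain_of_genus[as.character(g)], use.names = FALSE)))
  }

  # --- planted signal metabolites --------------------------------------
  all_cids <- 500000L + seq_len(cfg$n_metabolites)
  n_planted <- cfg$n_planted_drug_like + cfg$n_planted_marker_like
  planted_cids <- if (n_planted > 0L) utils::tail(all_cids, n_planted) else integer()
  background_cids <- setdiff(all_cids, planted_cids)

  set.seed(sub_seed(cfg, 53L))
  designated_for <- function(direction, what) {
    for (d in diseases) {
      if (length(panel_strains(d, direction)) > 0L) return(d)
    }
    stop(sprintf("infeasible config: no disease has any %sd strain to plant a %s metabolite",
                 direction, what), call. = FALSE)
  }
  truth_rows <- list()
  planted_links <- list()
  idx <- 0L
  if (cfg$n_planted_drug_like > 0L) {
    d <- designated_for("decrease", "drug-like")
    producers <- panel_strains(d, "decrease")
    for (k in seq_len(cfg$n_planted_drug_like)) {
      idx <- idx + 1L
      cid <- planted_cids[idx]
      truth_rows[[idx]] <- tibble::tibble(
        disease_id = d, metabolite_id = cid, intended_sign = -1L,
        producer_taxids = paste(producers, collapse = ";"))
      planted_links[[idx]] <- tibble::tibble(microbe_taxid = producers,
                                             metabolite_id = cid)
    }
  }
  if (cfg$n_planted_marker_like > 0L) {
    d <- designated_for("increase", "marker-like")
    producers <- panel_strains(d, "increase")
    for (k in seq_len(cfg$n_planted_marker_like)) {
      idx <- idx + 1L
      cid <- planted_cids[idx]
      truth_rows[[idx]] <- tibble::tibble(
        disease_id = d, metabolite_id = cid, intended_sign = 1L,
        producer_taxids = paste(producers, collapse = ";"))
      planted_links[[idx]] <- tibble::tibble(microbe_taxid = producers,
                                             metabolite_id = cid)
    }
  }
  ground_truth <- dplyr::bind_rows(truth_rows)
  if (nrow(ground_truth) == 0L) {
    ground_truth <- tibble::tibble(disease_id = character(),
                                   metabolite_id = integer(),
                                   intended_sign = integer(),
                                   producer_taxids = character())
  }

  # --- background production links -------------------------------------
  set.seed(sub_seed(cfg, 37L))
  strains <- sort(strain_rows$taxid)
  bg <- expand.grid(microbe_taxid = strains, metabolite_id = background_cids,
                    KEEP.OUT.ATTRS = FALSE)
  bg <- bg[order(bg$microbe_taxid, bg$metabolite_id), ]
  bg <- bg[stats::runif(nrow(bg)) < cfg$density_prod, ]
  mm <- dplyr::bind_rows(tibble::as_tibble(bg), dplyr::bind_rows(planted_links))
  mm <- dplyr::arrange(mm, .data$microbe_taxid, .data$metabolite_id)
  mm$microbe_name <- tax_name(taxonomy, mm$microbe_taxid)
  mm$metabolite_name <- sprintf("metabolite_%d", mm$metabolite_id - 500000L)

  # --- validation labels from ground truth -----------------------------
  set.seed(sub_seed(cfg, 71L))
  if (nrow(ground_truth) > 0L) {
    observed <- ifelse(ground_truth$intended_sign > 0, "up", "down")
    flip <- stats::runif(nrow(ground_truth)) < cfg$label_noise
    observed[flip] <- ifelse(observed[flip] == "up", "down", "up")
    validation <- tibble::tibble(
      disease_id = ground_truth$disease_id,
      metabolite_id = ground_truth$metabolite_id,
      observed_direction = observed,
      pmid = NA_integer_)
  } else {
    validation <- tibble::tibble(disease_id = character(),
                                 metabolite_id = integer(),
                                 observed_direction = character(),
                                 pmid = NA_integer_[0])
  }

  bundle <- list(disease_microbe = dm, microbe_metabolite = mm,
                 lineage = lineage, taxonomy = taxonomy,
                 validation = validation, ground_truth = ground_truth,
                 config = cfg)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    readr::write_tsv(dm, file.path(dir, "disease_microbe.tsv"), progress = FALSE)
    readr::write_tsv(mm, file.path(dir, "microbe_metabolite.tsv"), progress = FALSE)
    readr::write_tsv(lineage, file.path(dir, "lineage.tsv"), progress = FALSE)
    readr::write_tsv(validation, file.path(dir, "validation.tsv"), progress = FALSE)
    readr::write_tsv(ground_truth, file.path(dir, "ground_truth.tsv"), progress = FALSE)
  }
  bundle
}

#' Planted-signal recovery experiment
#'
#' Generates a bundle, scores it end to end, and measures how many planted
#' metabolites are recovered: a planted pair is *recovered* when it is
#' emitted, meaningful under `thresholds`, and its score sign matches the
#' intended sign. Also reports, per planted class, the fraction of
#' non-planted metabolites among the top-k strongest associations of the
#' designated disease (k = number planted in that class).
#'
#' @param cfg A [sim_config()] that plants at least one metabolite.
#' @param thresholds A [meaning_thresholds()] list.
#' @return A list with `recovery_fraction`, `false_top_rate`, `n_planted`
#'   and a per-planted `details` tibble.
#' @export
recovery_experiment <- function(cfg, thresholds = meaning_thresholds()) {
  stopifnot(cfg$n_planted_drug_like + cfg$n_planted_marker_like >= 1L)
  bundle <- generate_dataset(cfg)
  scored <- score_all(bundle$disease_microbe, bundle$microbe_metabolite,
                      bundle$taxonomy, thresholds)
  gt <- bundle$ground_truth
  details <- dplyr::left_join(
    gt, tibble::as_tibble(scored)[, c("disease_id", "metabolite_id", "s_as",
                                      "s_ac", "meaningful")],
    by = c("disease_id", "metabolite_id"))
  details$recovered <- !is.na(details$s_as) & details$meaningful &
    sign(details$s_as) == details$intended_sign
  details$recovered[is.na(details$recovered)] <- FALSE

  # top-k purity per (disease, intended sign) class
  false_top <- 0L
  top_total <- 0L
  for (cls in split(details, paste(details$disease_id, details$intended_sign))) {
    d <- cls$disease_id[[1]]
    sgn <- cls$intended_sign[[1]]
    k <- nrow(cls)
    rows <- tibble::as_tibble(scored)[scored$disease_id == d, ]
    rows <- rows[order(if (sgn < 0) rows$s_as else -rows$s_as,
                       -rows$s_ac, rows$metabolite_id), ]
    top <- utils::head(rows$metabolite_id, k)
    false_top <- false_top + sum(!top %in% cls$metabolite_id)
    top_total <- top_total + length(top)
  }
  list(recovery_fraction = mean(details$recovered),
       false_top_rate = if (top_total > 0L) false_top / top_total else NA_real_,
       n_planted = nrow(details),
       details = details)
}
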