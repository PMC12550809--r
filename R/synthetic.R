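# ---- synthetic monitoring campaigns with known ground truth --------------

#' Configuration for the synthetic-data generator
#'
#' The generator emulates the structure of multi-campaign WWTP monitoring
#' data: overlapping campaigns measuring overlapping substance sets across
#' plants, per-plant variability of logB, campaign-level offsets, LOQ
#' censoring of low concentrations, occasional breakthrough > 120%
#' artifacts, C- vs N-eliminating plants, and a planted, fingerprint-visible
#' structure-to-breakthrough signal (halogens raise breakthrough, hydroxyl
#' groups lower it, rings raise it mildly).
#'
#' @param n_substances number of distinct substances.
#' @param n_plants total plants; `frac_n_eliminating` of them carry a
#'   nitrifying-denitrifying step.
#' @param frac_n_eliminating fraction of N-eliminating plants.
#' @param n_datasets number of monitoring campaigns; plants are partitioned
#'   across campaigns.
#' @param overlap_fraction fraction of substances measured in more than one
#'   campaign.
#' @param effects named numeric: additive logB shifts for planted fragments
#'   (`halogen`, `hydroxyl`, `ring`).
#' @param baseline intercept of true logB before fragment effects.
#' @param logB_cap upper truncation of true logB (log10 units).
#' @param plant_sd SD of per-record plant noise (log10 units).
#' @param dataset_offset_sd SD of campaign offsets (log10 units).
#' @param loq_quantile fraction of lowest concentrations flagged below LOQ.
#' @param artifact_rate probability of a multiplicative effluent spike
#'   (x1.5-3) mimicking analytical error / in-plant formation.
#' @param c_elim_shift additive logB shift at C-only plants (reduced
#'   biotransformation, higher breakthrough).
#' @param frac_halogen,frac_hydroxyl,frac_ring prevalence of the planted
#'   fragments.
#' @param seed integer master seed; generation is bit-reproducible.
#' @return list of class `ww_genconfig`.
#' @export
generator_config <- function(n_substances = 300, n_plants = 20,
                             frac_n_eliminating = 0.7, n_datasets = 4,
                             overlap_fraction = 0.5,
                             effects = c(halogen = 0.5, hydroxyl = -0.4,
                                         ring = 0.2),
                             baseline = -0.8, logB_cap = 0.3,
                             plant_sd = 0.3, dataset_offset_sd = 0.1,
                             loq_quantile = 0.05, artifact_rate = 0.02,
                             c_elim_shift = 0.3,
                             frac_halogen = 0.5, frac_hydroxyl = 0.4,
                             frac_ring = 0.6, seed = 1) {
  stopifnot(n_substances >= 1, n_plants >= 2, n_datasets >= 1,
            overlap_fraction >= 0, overlap_fraction <= 1,
            loq_quantile >= 0, loq_quantile <= 1,
            artifact_rate >= 0, artifact_rate <= 1,
            plant_sd >= 0, dataset_offset_sd >= 0,
            all(c("halogen", "hydroxyl", "ring") %in% names(effects)))
  structure(as.list(environment()), class = "ww_genconfig")
}

# assemble a valid SMILES from planted fragment flags plus cosmetic
# variation; flags are known by construction
synth_smiles <- function(has_halogen, has_hydroxyl, has_ring,
                         hal, decoration, chain_len) {
  dec_has_oh <- decoration == "C(=O)O"
  groups <- c(if (has_halogen) hal,
              if (has_hydroxyl) "O",
              if (nzchar(decoration)) decoration)
  if (has_ring) {
    # substituted benzene; an alkyl tail adds variety when a slot is free
    if (chain_len > 1 && length(groups) < 3) {
      groups <- c(groups, strrep("C", chain_len - 1))
    }
    smi <- switch(as.character(length(groups)),
      "0" = "c1ccccc1",
      "1" = paste0("c1ccccc1", groups[1]),
      "2" = paste0("c1cc(", groups[1], ")ccc1", groups[2]),
      "3" = paste0("c1cc(", groups[1], ")cc(", groups[2], ")c1", groups[3]))
  } else {
    # alkane backbone; each group sits in its own branch so fragments
    # never merge (keeps the planted flags truthful)
    len <- max(chain_len, length(groups), 1)
    parts <- rep("C", len)
    for (j in seq_along(groups)) parts[j] <- paste0("C(", groups[j], ")")
    smi <- paste(parts, collapse = "")
  }
  list(smiles = smi, hydroxyl = has_hydroxyl || dec_has_oh)
}

#' Generate synthetic structures with known fragment flags
#'
#' Builds `n_substances` distinct valid structures combinatorially from a
#' small fragment library (substituted benzenes, phenols, aliphatic
#' alcohols/acids/amines/ethers/nitriles/guanidines, halogenated variants)
#' so that the planted fragment flags (halogen, hydroxyl, ring) are known
#' exactly. All structures pass standardization.
#'
#' @param config a [generator_config()].
#' @return list with `structures` (standardized data.frame, see
#'   [standardize_structures()]) and `truth` (data.frame `substance_id`,
#'   `has_halogen`, `has_hydroxyl`, `has_ring`).
#' @export
generate_structures <- function(config) {
  stopifnot(inherits(config, "ww_genconfig"))
  set.seed(config$seed)
  n <- config$n_substances
  hal_choices <- c("F", "Cl", "Br")
  decorations <- c("", "C", "CC", "N", "C(=O)O", "OC", "C#N", "C(=O)N",
                   "NC(=N)N")
  seen <- character(0)
  rows <- vector("list", n)
  k <- 0L
  tries <- 0L
  while (k < n) {
    tries <- tries + 1L
    if (tries > 200L * n) stop("could not generate enough distinct structures")
    hh <- runif(1) < config$frac_halogen
    ho <- runif(1) < config$frac_hydroxyl
    hr <- runif(1) < config$frac_ring
    s <- synth_smiles(hh, ho, hr,
                      hal = sample(hal_choices, 1),
                      decoration = sample(decorations, 1),
                      chain_len = sample.int(8, 1))
    if (s$smiles %in% seen) next
    seen <- c(seen, s$smiles)
    k <- k + 1L
    rows[[k]] <- data.frame(substance_id = sprintf("syn%04d", k),
                            smiles = s$smiles,
                            has_halogen = hh, has_hydroxyl = s$hydroxyl,
                            has_ring = hr, stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, rows)
  structures <- standardize_structures(truth$smiles, truth$substance_id)
  list(structures = structures,
       truth = truth[c("substance_id", "has_halogen", "has_hydroxyl",
                       "has_ring")])
}

true_logB <- function(truth, config) {
  eff <- config$effects
  lb <- config$baseline +
    truth$has_halogen * eff[["halogen"]] +
    truth$has_hydroxyl * eff[["hydroxyl"]] +
    truth$has_ring * eff[["ring"]]
  pmin(lb, config$logB_cap)
}

#' Generate synthetic monitoring records
#'
#' True logB per substance is `baseline + sum(fragment effects)` truncated
#' at `logB_cap`; each record observes it plus per-record plant noise, its
#' campaign's offset, a C-eliminating shift where applicable, and an
#' occasional multiplicative artifact spike. Influent concentrations are
#' lognormal; effluent concentrations are back-calculated from the observed
#' breakthrough, and the lowest `loq_quantile` of each concentration column
#' is flagged below the LOQ.
#'
#' @param gen output of [generate_structures()] (or a truth data.frame with
#'   the fragment flag columns).
#' @param config the same [generator_config()].
#' @return list with `records` (monitoring CSV schema), `plant_meta`,
#'   `truth` (flags plus `logB_true`), `dataset_offsets`.
#' @export
generate_monitoring <- function(gen, config) {
  stopifnot(inherits(config, "ww_genconfig"))
  truth <- if (is.data.frame(gen)) gen else gen$truth
  set.seed(config$seed + 1L)
  n_sub <- nrow(truth)
  truth$logB_true <- true_logB(truth, config)

  plants <- data.frame(
    plant_id = sprintf("P%02d", seq_len(config$n_plants)),
    n_eliminating = seq_len(config$n_plants) <=
      round(config$frac_n_eliminating * config$n_plants),
    stringsAsFactors = FALSE)
  ds_ids <- paste0("DS", seq_len(config$n_datasets))
  plant_ds <- ds_ids[rep_len(seq_len(config$n_datasets), config$n_plants)]
  offsets <- setNames(rnorm(config$n_datasets, 0, config$dataset_offset_sd),
                      ds_ids)

  # membership: every substance in one primary campaign; a fraction appears
  # in additional campaigns (overlapping coverage)
  membership <- lapply(seq_len(n_sub), function(i) {
    prim <- sample(ds_ids, 1)
    if (config$n_datasets > 1 && runif(1) < config$overlap_fraction) {
      unique(c(prim, sample(setdiff(ds_ids, prim),
                            sample.int(config$n_datasets - 1, 1))))
    } else prim
  })

  rows <- list()
  for (i in seq_len(n_sub)) {
    for (ds in membership[[i]]) {
      for (pl in which(plant_ds == ds)) {
        logB <- truth$logB_true[i] + rnorm(1, 0, config$plant_sd) +
          offsets[[ds]] +
          (!plants$n_eliminating[pl]) * config$c_elim_shift
        B <- 10^logB
        if (runif(1) < config$artifact_rate) B <- B * runif(1, 1.5, 3)
        c_inf <- 10^rnorm(1, 0, 0.5)
        rows[[length(rows) + 1]] <- data.frame(
          substance_id = truth$substance_id[i],
          plant_id = plants$plant_id[pl],
          dataset_id = ds,
          c_influent = c_inf,
          c_effluent = c_inf * B,
          stringsAsFactors = FALSE)
      }
    }
  }
  rec <- do.call(rbind, rows)
  rec$influent_below_loq <- rec$c_influent <=
    quantile(rec$c_influent, config$loq_quantile)
  rec$effluent_below_loq <- rec$c_effluent <=
    quantile(rec$c_effluent, config$loq_quantile)
  if (config$loq_quantile == 0) {
    rec$influent_below_loq <- rec$effluent_below_loq <- FALSE
  }
  rownames(rec) <- NULL
  list(records = rec[monitoring_cols], plant_meta = plants,
       truth = truth, dataset_offsets = offsets)
}

#' Analytic generalization ceiling of a synthetic data set
#'
#' The endpoint (median of noisy per-plant logB values) differs from the
#' true logB by median noise; no model predicting from structure alone can
#' beat that. The ceiling is `1 - MSE_irreducible / var(endpoint)` where
#' `MSE_irreducible = mean((median_logB - logB_true)^2)`, computed directly
#' from the generator's ground truth.
#'
#' @param summaries substance summaries from [summarize_substances()].
#' @param truth truth table from [generate_monitoring()].
#' @return the R-squared ceiling (scalar).
#' @export
generative_r2_ceiling <- function(summaries, truth) {
  m <- merge(summaries, truth, by = "substance_id")
  stopifnot(nrow(m) > 1)
  1 - mean((m$median_logB - m$logB_true)^2) / var(m$median_logB)
}

#' Write a synthetic data set to CSV files
#'
#' Emits exactly the schemas consumed by the monitoring and structure
#' readers plus the ground truth (for test harnesses only).
#' @param gen output of [generate_structures()].
#' @param mon output of [generate_monitoring()].
#' @param dir output directory (created if needed).
#' @return invisible named vector of file paths.
#' @export
write_synthetic <- function(gen, mon, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(structures = file.path(dir, "structures.csv"),
             monitoring = file.path(dir, "monitoring.csv"),
             plants = file.path(dir, "plants.csv"),
             truth = file.path(dir, "ground_truth.csv"))
  smiles_df <- data.frame(substance_id = gen$structures$substance_id,
                          smiles = gen$structures$smiles_input,
                          stringsAsFactors = FALSE)
  write.csv(smiles_df, paths["structures"], row.names = FALSE)
  write.csv(mon$records, paths["monitoring"], row.names = FALSE)
  write.csv(mon$plant_meta, paths["plants"], row.names = FALSE)
  write.csv(mon$truth, paths["truth"], row.names = FALSE)
  invisible(paths)
}
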