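# ---- data curation: base scheme plus criteria I-V ------------------------

#' Curation criteria configuration
#'
#' Five additional curation criteria applied on top of the base scheme
#' (duplicate merging, structure standardization, rejection of
#' influent-below-LOQ records):
#' \describe{
#'   \item{I}{drop substances with breakthrough values from fewer than
#'     `min_plants` plants (default 3) -- too few plants to be
#'     representative.}
#'   \item{II}{drop substances with breakthrough exceeding `max_B`
#'     (default 1.2, i.e. 120\%) -- likely analytical error or in-plant
#'     formation. By default any plant-level value above the cap fires
#'     (`ii_scope = "any"`); `"median"` tests only the substance median.}
#'   \item{III}{drop substances whose across-plant SD of logB is `>=
#'     max_sd_logB` (default 0.7 log10 units); substances with undefined SD
#'     (a single plant) are kept -- missing SD is not high SD.}
#'   \item{IV}{drop individual entries whose effluent was below the LOQ,
#'     then re-summarize (entry-level, applied before the substance-level
#'     criteria).}
#'   \item{V}{drop highly sorbing (K_OC > `koc_threshold`, default 4000
#'     L/kg) or highly volatile (Henry > `henry_threshold`, default 1e-5
#'     atm m^3/mol) substances, whose removal is not biodegradation-driven.}
#' }
#'
#' @param use_I,use_II,use_III,use_IV,use_V logical switches.
#' @param min_plants,max_B,max_sd_logB,koc_threshold,henry_threshold
#'   thresholds as described above.
#' @param ii_scope `"any"` (any plant-level value) or `"median"`.
#' @param v_missing `"error"` (default) or `"drop"` for substances missing a
#'   property row when criterion V is on.
#' @return object of class `curation_criteria`.
#' @export
curation_criteria <- function(use_I = TRUE, use_II = TRUE, use_III = TRUE,
                              use_IV = TRUE, use_V = TRUE,
                              min_plants = 3, max_B = 1.2,
                              max_sd_logB = 0.7, koc_threshold = 4000,
                              henry_threshold = 1e-5,
                              ii_scope = c("any", "median"),
                              v_missing = c("error", "drop")) {
  stopifnot(min_plants >= 1, max_B > 0, max_sd_logB > 0,
            koc_threshold > 0, henry_threshold > 0)
  structure(list(use_I = use_I, use_II = use_II, use_III = use_III,
                 use_IV = use_IV, use_V = use_V,
                 min_plants = min_plants, max_B = max_B,
                 max_sd_logB = max_sd_logB,
                 koc_threshold = koc_threshold,
                 henry_threshold = henry_threshold,
                 ii_scope = match.arg(ii_scope),
                 v_missing = match.arg(v_missing)),
            class = "curation_criteria")
}

#' Read a substance property table (for curation criterion V)
#'
#' Schema: `substance_id`, `koc` (organic carbon-water partition
#' coefficient, L/kg), `henry` (Henry's law constant, atm m^3/mol), optional
#' `source` tag (e.g. the predictor version that produced the values).
#' Property prediction itself is out of scope; values are consumed as data.
#' @param path CSV file path.
#' @return data.frame, one row per substance.
#' @export
read_property_table <- function(path) {
  if (!file.exists(path)) stop("property table not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("substance_id", "koc", "henry") %in% names(df)))
  if (anyDuplicated(df$substance_id)) {
    stop("duplicate substance_id in property table")
  }
  df
}

#' Apply curation criteria to substance summaries
#'
#' Entry-level criterion IV is applied first (drop effluent-below-LOQ
#' entries and re-summarize), then the substance-level criteria I, II, III
#' and V; with that fixed order the result is independent of the order in
#' which substance-level criteria are listed. Every dropped substance
#' carries at least one reason in the audit trail.
#'
#' @param summaries substance summaries from [summarize_substances()].
#' @param values breakthrough values from [compute_breakthrough()] (needed
#'   for criterion IV's re-summarization).
#' @param criteria a [curation_criteria()] object.
#' @param props property table (see [read_property_table()]); required iff
#'   `use_V`.
#' @param plant_filter,per_plant passed to [summarize_substances()] when
#'   criterion IV re-summarizes.
#' @return list with `summaries` (curated), `audit` (data.frame
#'   `substance_id`, `kept`, `reasons` -- comma-separated criteria that
#'   fired), and `n_dropped`.
#' @export
apply_criteria <- function(summaries, values, criteria, props = NULL,
                           plant_filter = NULL, per_plant = TRUE) {
  stopifnot(inherits(criteria, "curation_criteria"))
  if (criteria$use_V && is.null(props)) {
    stop("curation criterion V requires a property table (K_OC, Henry)",
         call. = FALSE)
  }
  ids0 <- summaries$substance_id
  reasons <- setNames(vector("list", length(ids0)), ids0)
  s <- summaries

  if (criteria$use_IV) {
    keep_vals <- values[!values$effluent_below_loq, , drop = FALSE]
    s <- summarize_substances(keep_vals, plant_filter = plant_filter,
                              per_plant = per_plant)
    s <- s[s$substance_id %in% ids0, , drop = FALSE]
    gone <- setdiff(ids0, s$substance_id)
    for (id in gone) reasons[[id]] <- c(reasons[[id]], "IV")
  }

  fire <- function(ids, crit) {
    for (id in ids) reasons[[id]] <<- c(reasons[[id]], crit)
  }
  if (criteria$use_I) {
    fire(s$substance_id[s$n_plants < criteria$min_plants], "I")
  }
  if (criteria$use_II) {
    hit <- if (criteria$ii_scope == "any") {
      s$max_B > criteria$max_B
    } else {
      10^s$median_logB > criteria$max_B
    }
    fire(s$substance_id[hit], "II")
  }
  if (criteria$use_III) {
    hit <- !is.na(s$sd_logB) & s$sd_logB >= criteria$max_sd_logB
    fire(s$substance_id[hit], "III")
  }
  if (criteria$use_V) {
    idx <- match(s$substance_id, props$substance_id)
    missing_prop <- is.na(idx)
    if (any(missing_prop) && criteria$v_missing == "error") {
      stop("criterion V: no property row for substance(s): ",
           paste(head(s$substance_id[missing_prop], 5), collapse = ", "),
           call. = FALSE)
    }
    koc <- props$koc[idx]
    henry <- props$henry[idx]
    hit <- missing_prop | (!is.na(koc) & koc > criteria$koc_threshold) |
      (!is.na(henry) & henry > criteria$henry_threshold)
    fire(s$substance_id[hit], "V")
  }

  dropped_ids <- names(reasons)[lengths(reasons) > 0]
  curated <- s[!(s$substance_id %in% dropped_ids), , drop = FALSE]
  rownames(curated) <- NULL
  audit <- data.frame(substance_id = ids0,
                      kept = !(ids0 %in% dropped_ids),
                      reasons = vapply(reasons, function(r)
                        paste(r, collapse = ","), character(1)),
                      stringsAsFactors = FALSE)
  rownames(audit) <- NULL
  list(summaries = curated, audit = audit, n_dropped = length(dropped_ids))
}

criteria_from_bits <- function(bits, base = curation_criteria()) {
  # bits: named logical vector over c("I","II","III","IV","V")
  base$use_I <- isTRUE(bits[["I"]]); base$use_II <- isTRUE(bits[["II"]])
  base$use_III <- isTRUE(bits[["III"]]); base$use_IV <- isTRUE(bits[["IV"]])
  base$use_V <- isTRUE(bits[["V"]])
  base
}

#' Sweep all curation-criteria combinations
#'
#' Evaluates how each of the 2^k combinations of curation criteria changes
#' model performance on a fixed held-out pool. The pool is the
#' highest-confidence set (all applicable criteria on), split into
#' `n_folds` disjoint test folds. For each combination, the model factory is
#' trained on the correspondingly curated data minus the current test fold
#' and scored on the fold; per-combination mean R^2, mean RMSE and training
#' size are reported. Test-fold substances never enter any training set.
#'
#' @param values breakthrough values from [compute_breakthrough()].
#' @param fingerprints a fingerprint object from [compute_fingerprints()]
#'   covering every substance that can survive curation.
#' @param model_factory `function(X, y)` returning an object with a
#'   `predict(object, X)` method (see [forest_factory()]).
#' @param props property table; when `NULL`, criterion V is excluded from
#'   the sweep (2^4 combinations).
#' @param n_folds number of disjoint test folds from the pool.
#' @param seed integer seed fixing the fold split.
#' @param plant_filter,per_plant passed through to summarization.
#' @param base criteria object supplying thresholds.
#' @return data.frame with one row per combination: `combination` (label
#'   like "I+III", "none"), `use_I`..`use_V`, `n_train` (mean over folds),
#'   `mean_R2`, `mean_RMSE`, `n_pool`.
#' @export
criteria_sweep <- function(values, fingerprints, model_factory,
                           props = NULL, n_folds = 5, seed = 1,
                           plant_filter = NULL, per_plant = TRUE,
                           base = curation_criteria()) {
  crits <- c("I", "II", "III", "IV")
  if (!is.null(props)) crits <- c(crits, "V")
  summaries <- summarize_substances(values, plant_filter = plant_filter,
                                    per_plant = per_plant)
  all_on <- criteria_from_bits(setNames(rep(TRUE, 5),
                                        c("I", "II", "III", "IV", "V")),
                               base)
  all_on$use_V <- !is.null(props)
  pool <- apply_criteria(summaries, values, all_on, props = props,
                         plant_filter = plant_filter,
                         per_plant = per_plant)$summaries
  if (nrow(pool) < n_folds) stop("high-confidence pool too small to split")
  fold <- make_folds(nrow(pool), n_folds, seed = seed)
  fpm <- fingerprint_matrix(fingerprints)

  combos <- expand.grid(rep(list(c(FALSE, TRUE)), length(crits)))
  names(combos) <- crits
  rows <- lapply(seq_len(nrow(combos)), function(ci) {
    bits <- setNames(as.logical(combos[ci, ]), crits)
    full <- setNames(rep(FALSE, 5), c("I", "II", "III", "IV", "V"))
    full[names(bits)] <- bits
    crit <- criteria_from_bits(full, base)
    cur <- apply_criteria(summaries, values, crit, props = props,
                          plant_filter = plant_filter,
                          per_plant = per_plant)$summaries
    r2s <- rmses <- ntr <- rep(NA_real_, n_folds)
    for (f in seq_len(n_folds)) {
      test_ids <- pool$substance_id[fold == f]
      train <- cur[!(cur$substance_id %in% test_ids), , drop = FALSE]
      train <- train[train$substance_id %in% rownames(fpm), , drop = FALSE]
      test <- pool[fold == f & pool$substance_id %in% rownames(fpm), ,
                   drop = FALSE]
      if (nrow(train) == 0 || nrow(test) == 0) next
      stopifnot(length(intersect(train$substance_id,
                                 test$substance_id)) == 0)
      mdl <- model_factory(fpm[train$substance_id, , drop = FALSE],
                           train$median_logB)
      pred <- predict(mdl, fpm[test$substance_id, , drop = FALSE])
      r2s[f] <- r_squared(test$median_logB, pred)
      rmses[f] <- rmse(test$median_logB, pred)
      ntr[f] <- nrow(train)
    }
    lab <- paste(crits[bits], collapse = "+")
    data.frame(combination = if (nzchar(lab)) lab else "none",
               use_I = full[["I"]], use_II = full[["II"]],
               use_III = full[["III"]], use_IV = full[["IV"]],
               use_V = full[["V"]],
               n_train = mean(ntr, na.rm = TRUE),
               mean_R2 = mean(r2s, na.rm = TRUE),
               mean_RMSE = mean(rmses, na.rm = TRUE),
               n_pool = nrow(pool),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
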