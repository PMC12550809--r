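# ---- breakthrough computation and per-substance endpoint -----------------

monitoring_cols <- c("substance_id", "plant_id", "dataset_id",
                     "c_influent", "c_effluent",
                     "influent_below_loq", "effluent_below_loq")

#' Read a monitoring table from CSV
#'
#' Strict schema: `substance_id`, `plant_id`, `dataset_id`, `c_influent`,
#' `c_effluent`, `influent_below_loq`, `effluent_below_loq`. Concentrations
#' may be in any unit (including semiquantitative peak areas) but influent
#' and effluent of one record must share the unit, because breakthrough is a
#' ratio; that consistency cannot be checked from the data and is the
#' caller's responsibility.
#'
#' @param path CSV file path.
#' @return data.frame with the columns above, LOQ flags as logical.
#' @export
read_monitoring <- function(path) {
  if (!file.exists(path)) stop("monitoring file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(monitoring_cols, names(df))
  if (length(miss) > 0) {
    stop("monitoring CSV missing column(s): ", paste(miss, collapse = ", "))
  }
  df$influent_below_loq <- as.logical(df$influent_below_loq)
  df$effluent_below_loq <- as.logical(df$effluent_below_loq)
  validate_monitoring(df)
  df[monitoring_cols]
}

validate_monitoring <- function(records) {
  stopifnot(is.data.frame(records),
            all(monitoring_cols %in% names(records)))
  if (any(!is.finite(records$c_influent)) ||
      any(!is.finite(records$c_effluent))) {
    stop("non-finite concentrations in monitoring records")
  }
  if (any(records$c_influent <= 0)) {
    stop("c_influent must be > 0 (found ", sum(records$c_influent <= 0),
         " violations)")
  }
  if (any(records$c_effluent < 0)) stop("c_effluent must be >= 0")
  invisible(records)
}

#' Read plant metadata from CSV
#'
#' Schema: `plant_id`, `n_eliminating` (logical; TRUE when the plant has a
#' nitrifying-denitrifying step), optional `country`.
#' @param path CSV file path.
#' @return data.frame with one row per plant.
#' @export
read_plant_meta <- function(path) {
  if (!file.exists(path)) stop("plant metadata file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("plant_id", "n_eliminating") %in% names(df)))
  df$n_eliminating <- as.logical(df$n_eliminating)
  if (anyDuplicated(df$plant_id)) stop("duplicate plant_id in plant metadata")
  df
}

#' Compute per-record breakthrough
#'
#' Breakthrough is the quotient of the effluent and influent concentration,
#' B = C_effluent / C_influent, interpreted as the fraction of a substance
#' that survives treatment; the model target is logB = log10(B). Records
#' whose influent concentration is below the limit of quantification are
#' rejected (the ratio denominator is unreliable). Effluent values below the
#' LOQ are still used -- the measured value enters the ratio -- and the flag
#' is propagated so curation criterion IV can act on it later. A zero
#' effluent concentration makes logB undefined and rejects the record unless
#' `zero_effluent_floor` substitutes a positive value (off by default; the
#' reference workflow never imputes).
#'
#' @param records monitoring data.frame (see [read_monitoring()]).
#' @param zero_effluent_floor optional positive number substituted for zero
#'   effluent concentrations (e.g. half the LOQ); `NULL` rejects such records.
#' @return data.frame of accepted values with columns `substance_id`,
#'   `plant_id`, `dataset_id`, `B`, `logB`, `effluent_below_loq`; rejected
#'   records are attached as `attr(, "rejected")` with a `reason` column.
#' @examples
#' rec <- data.frame(substance_id = "a", plant_id = "p", dataset_id = "d",
#'                   c_influent = 10, c_effluent = 1,
#'                   influent_below_loq = FALSE, effluent_below_loq = FALSE)
#' compute_breakthrough(rec)$logB  # -1
#' @export
compute_breakthrough <- function(records, zero_effluent_floor = NULL) {
  validate_monitoring(records)
  rec <- records
  reason <- rep(NA_character_, nrow(rec))
  reason[rec$influent_below_loq] <- "influent below LOQ"
  if (!is.null(zero_effluent_floor)) {
    stopifnot(zero_effluent_floor > 0)
    rec$c_effluent[rec$c_effluent == 0] <- zero_effluent_floor
  }
  reason[is.na(reason) & rec$c_effluent == 0] <- "zero effluent"
  ok <- is.na(reason)
  out <- data.frame(substance_id = rec$substance_id[ok],
                    plant_id = rec$plant_id[ok],
                    dataset_id = rec$dataset_id[ok],
                    B = rec$c_effluent[ok] / rec$c_influent[ok],
                    effluent_below_loq = rec$effluent_below_loq[ok],
                    stringsAsFactors = FALSE)
  out$logB <- log10(out$B)
  out <- out[c("substance_id", "plant_id", "dataset_id", "B", "logB",
               "effluent_below_loq")]
  rejected <- cbind(rec[!ok, , drop = FALSE],
                    reason = reason[!ok])
  rownames(out) <- rownames(rejected) <- NULL
  attr(out, "rejected") <- rejected
  out
}

#' Aggregate breakthrough values to the per-substance endpoint
#'
#' The model target is the median breakthrough across plants. When a plant
#' contributed replicate records, aggregation is two-stage by default:
#' median of the plant's per-record logB first, then the median across
#' plants (`per_plant = FALSE` switches to a flat median over all records).
#' The spread across plants (`sd_logB`, sample SD of the per-plant logB
#' values, log10 units) feeds curation criterion III, and the largest
#' per-plant B feeds criterion II.
#'
#' @param values breakthrough data.frame from [compute_breakthrough()].
#' @param plant_filter optional character vector of plant ids to keep (e.g.
#'   the N-eliminating plants); `NULL` keeps all.
#' @param per_plant logical; aggregate replicates within plant first.
#' @return data.frame with one row per substance: `substance_id`,
#'   `median_logB`, `n_plants`, `sd_logB` (NA when fewer than 2 plants),
#'   `max_B`, `any_effluent_below_loq`.
#' @export
summarize_substances <- function(values, plant_filter = NULL,
                                 per_plant = TRUE) {
  stopifnot(is.data.frame(values),
            all(c("substance_id", "plant_id", "B", "logB",
                  "effluent_below_loq") %in% names(values)))
  v <- values
  if (!is.null(plant_filter)) v <- v[v$plant_id %in% plant_filter, ,
                                     drop = FALSE]
  if (nrow(v) == 0) {
    message("summarize_substances: no values left after plant filter")
    return(data.frame(substance_id = character(), median_logB = numeric(),
                      n_plants = integer(), sd_logB = numeric(),
                      max_B = numeric(), any_effluent_below_loq = logical(),
                      stringsAsFactors = FALSE))
  }
  one <- function(d) {
    if (per_plant) {
      plant_logB <- tapply(d$logB, d$plant_id, median)
    } else {
      plant_logB <- setNames(d$logB, d$plant_id)
    }
    plant_B <- 10^plant_logB  # keep B/logB coherent after aggregation
    n_plants <- length(unique(d$plant_id))
    data.frame(substance_id = d$substance_id[1],
               median_logB = median(plant_logB),
               n_plants = n_plants,
               sd_logB = if (n_plants >= 2 && per_plant) sd(plant_logB)
                         else if (length(plant_logB) >= 2) sd(plant_logB)
                         else NA_real_,
               max_B = max(plant_B),
               any_effluent_below_loq = any(d$effluent_below_loq),
               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(split(v, v$substance_id), one))
  out <- out[order(out$substance_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# one-way variance components by method of moments
var_components <- function(y, group) {
  group <- as.character(group)
  k <- length(unique(group))
  n <- length(y)
  if (k < 2 || n <= k) {
    return(c(between = NA_real_, within = var(y)))
  }
  gm <- tapply(y, group, mean)
  gn <- tapply(y, group, length)
  grand <- mean(y)
  msb <- sum(gn * (gm[names(gn)] - grand)^2) / (k - 1)
  msw <- sum((y - gm[group])^2) / (n - k)
  n0 <- (n - sum(gn^2) / n) / (k - 1)
  c(between = max(0, (msb - msw) / n0), within = msw)
}

#' Batch-effect check across monitoring campaigns
#'
#' Before pooling campaigns into one endpoint per substance, this check asks
#' whether between-substance variability dominates between-campaign
#' variability. Only substances with at least `min_per_dataset` breakthrough
#' values in each of two or more datasets enter. For each eligible substance
#' a one-way variance decomposition of its logB values by dataset is
#' reported; pooled over the eligible subset, the between-substance
#' component is estimated by a one-way decomposition grouped by substance,
#' and the between-dataset component by a one-way decomposition of the
#' substance-centered values grouped by dataset (method-of-moments
#' estimators throughout, negative estimates truncated at zero).
#'
#' @param values breakthrough data.frame from [compute_breakthrough()].
#' @param min_per_dataset minimum values per dataset for eligibility.
#' @return list with `per_substance` data.frame (`substance_id`,
#'   `n_datasets`, `between_dataset_var`, `within_dataset_var`),
#'   `var_between_substances`, `var_between_datasets`, `n_eligible`.
#' @export
batch_effect_check <- function(values, min_per_dataset = 3) {
  stopifnot(min_per_dataset >= 1)
  counts <- table(values$substance_id, values$dataset_id)
  eligible <- rownames(counts)[rowSums(counts >= min_per_dataset) >= 2]
  if (length(eligible) == 0) {
    message("batch_effect_check: no eligible substances")
    return(list(per_substance = data.frame(substance_id = character(),
                                           n_datasets = integer(),
                                           between_dataset_var = numeric(),
                                           within_dataset_var = numeric()),
                var_between_substances = NA_real_,
                var_between_datasets = NA_real_,
                n_eligible = 0L))
  }
  v <- values[values$substance_id %in% eligible, , drop = FALSE]
  # keep only dataset cells meeting the minimum, so sparse cells do not
  # masquerade as replication
  cell_n <- ave(v$logB, v$substance_id, v$dataset_id, FUN = length)
  v <- v[cell_n >= min_per_dataset, , drop = FALSE]
  per <- do.call(rbind, lapply(split(v, v$substance_id), function(d) {
    vc <- var_components(d$logB, d$dataset_id)
    data.frame(substance_id = d$substance_id[1],
               n_datasets = length(unique(d$dataset_id)),
               between_dataset_var = unname(vc["between"]),
               within_dataset_var = unname(vc["within"]),
               stringsAsFactors = FALSE)
  }))
  rownames(per) <- NULL
  vc_sub <- var_components(v$logB, v$substance_id)
  centered <- v$logB - ave(v$logB, v$substance_id)
  vc_ds <- var_components(centered, v$dataset_id)
  list(per_substance = per,
       var_between_substances = unname(vc_sub["between"]),
       var_between_datasets = unname(vc_ds["between"]),
       n_eligible = length(eligible))
}
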