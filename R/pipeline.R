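# ---- end-to-end pipeline orchestration -----------------------------------

#' Read a flat key-value run configuration
#'
#' Plain text, one `key = value` per line, `#` comments allowed. Values are
#' auto-typed (logical, numeric, else string). Recognized keys: input paths
#' (`monitoring`, `structures`, `plants`, `properties`, `rules`), `outdir`,
#' `seed`, `descriptor` (MACCS/ECFP/PATH_HASHED/EPFP), curation switches
#' mirroring [curation_criteria()] fields (`use_I` .. `use_V`, `min_plants`,
#' `max_B`, `max_sd_logB`, `koc_threshold`, `henry_threshold`), model
#' settings (`n_trees`, `max_depth`, `min_split`), and
#' `restrict_n_eliminating` (default TRUE when plant metadata is given).
#'
#' @param path configuration file.
#' @return named list of class `ww_runconfig`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([A-Za-z0-9_]+)\\s*=\\s*(.*)$", lines))
  bad <- lines[vapply(kv, length, integer(1)) != 3]
  if (length(bad) > 0) {
    stop("config line(s) not of the form key = value: ",
         paste(bad, collapse = "; "), call. = FALSE)
  }
  cfg <- lapply(kv, function(m) {
    v <- trimws(m[3])
    if (toupper(v) %in% c("TRUE", "FALSE")) return(as.logical(v))
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) return(num)
    v
  })
  names(cfg) <- vapply(kv, `[`, character(1), 2)
  cfg <- cfg[!duplicated(names(cfg), fromLast = TRUE)]  # last setting wins
  cfg$config_source <- path
  class(cfg) <- "ww_runconfig"
  cfg
}

config_criteria <- function(cfg) {
  base <- curation_criteria()
  crit_keys <- intersect(names(cfg),
                         c("use_I", "use_II", "use_III", "use_IV", "use_V",
                           "min_plants", "max_B", "max_sd_logB",
                           "koc_threshold", "henry_threshold"))
  for (k in crit_keys) base[[k]] <- cfg[[k]]
  base
}

plog <- function(log_lines, ...) c(log_lines, paste0(...))

#' Run the full breakthrough-modeling pipeline
#'
#' Stages, in order: standardize structures, deduplicate, compute
#' breakthrough, summarize to the per-substance endpoint (restricted to
#' N-eliminating plants when plant metadata allows), apply curation
#' criteria, featurize, train a bias-corrected forest bundle, predict the
#' training set with confidence, and export SHAP attributions. All outputs,
#' a per-stage count log and a verbatim copy of the configuration are
#' written to `outdir`; rerunning with the same inputs and seed reproduces
#' them bit-identically. Every substance entering the pipeline ends up
#' either in the final data set or with a named drop reason in the log.
#'
#' @param config a `ww_runconfig`, a path to one, or an equivalent list.
#' @return invisibly, a list with the main in-memory artifacts
#'   (`structures`, `values`, `summaries`, `curated`, `fingerprints`,
#'   `bundle`, `predictions`, `paths`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  cfg <- config
  need <- setdiff(c("monitoring", "structures", "outdir"), names(cfg))
  if (length(need) > 0) {
    stop("config missing required key(s): ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  for (k in intersect(c("monitoring", "structures", "plants", "properties",
                        "rules"), names(cfg))) {
    if (!file.exists(cfg[[k]])) {
      stop("input file for '", k, "' not found: ", cfg[[k]], call. = FALSE)
    }
  }
  seed <- as.integer(cfg$seed %||% 1)
  descriptor <- cfg$descriptor %||% "MACCS"
  outdir <- cfg$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  lg <- character(0)

  structures <- read_structures(cfg$structures)
  lg <- plog(lg, "structures: ", nrow(structures), " read, ",
             sum(!structures$valid), " invalid")
  records <- read_monitoring(cfg$monitoring)
  lg <- plog(lg, "monitoring: ", nrow(records), " records, ",
             length(unique(records$substance_id)), " substances")
  dd <- deduplicate_substances(structures, records)
  structures <- dd$structures
  records <- dd$records
  lg <- plog(lg, "dedup: ", dd$n_merged, " substances merged")

  values <- compute_breakthrough(records)
  rej <- attr(values, "rejected")
  lg <- plog(lg, "breakthrough: ", nrow(values), " values, ",
             nrow(rej), " records rejected (",
             paste(names(table(rej$reason)), table(rej$reason),
                   sep = "=", collapse = ", "), ")")

  plant_filter <- NULL
  if (!is.null(cfg$plants)) {
    plants <- read_plant_meta(cfg$plants)
    if (isTRUE(cfg$restrict_n_eliminating %||% TRUE)) {
      plant_filter <- plants$plant_id[plants$n_eliminating]
      lg <- plog(lg, "plant filter: ", length(plant_filter),
                 "/", nrow(plants), " N-eliminating plants retained")
    }
  }
  summaries <- summarize_substances(values, plant_filter = plant_filter)
  lg <- plog(lg, "summaries: ", nrow(summaries), " substances with endpoint")

  props <- if (!is.null(cfg$properties)) {
    read_property_table(cfg$properties)
  }
  criteria <- config_criteria(cfg)
  if (criteria$use_V && is.null(props)) {
    stop("curation criterion V is enabled but no property table ",
         "(`properties`) was provided", call. = FALSE)
  }
  cur <- apply_criteria(summaries, values, criteria, props = props,
                        plant_filter = plant_filter)
  lg <- plog(lg, "curation: ", nrow(cur$summaries), " kept, ",
             cur$n_dropped, " dropped")
  drop_tab <- table(unlist(strsplit(
    cur$audit$reasons[!cur$audit$kept], ",")))
  if (length(drop_tab) > 0) {
    lg <- plog(lg, "  drop reasons: ",
               paste(names(drop_tab), drop_tab, sep = "=", collapse = ", "))
  }

  ruleset <- if (identical(descriptor, "EPFP")) {
    if (!is.null(cfg$rules)) read_ruleset(cfg$rules) else read_ruleset()
  }
  fp <- compute_fingerprints(structures, kind = descriptor,
                             ruleset = ruleset)
  fpm <- fingerprint_matrix(fp)
  lg <- plog(lg, "fingerprints: ", descriptor, ", ", ncol(fpm), " bits, ",
             count_unique_fingerprints(fp)$n_unique, " unique rows")

  train <- cur$summaries[cur$summaries$substance_id %in% rownames(fpm), ,
                         drop = FALSE]
  hyper <- list(n_trees = as.integer(cfg$n_trees %||% 300),
                max_depth = if (!is.null(cfg$max_depth)) cfg$max_depth
                            else Inf,
                min_split = as.integer(cfg$min_split %||% 2))
  bundle <- train_model(fpm[train$substance_id, , drop = FALSE],
                        train$median_logB, hyper = hyper,
                        descriptor_kind = descriptor, seed = seed,
                        metadata = list(criteria = unclass(criteria)))
  lg <- plog(lg, "model: forest of ", hyper$n_trees, " trees on ",
             nrow(train), " substances")

  preds <- predict(bundle, fpm[train$substance_id, , drop = FALSE])
  preds$truth <- train$median_logB
  att <- shap_attributions(bundle)

  paths <- c(structures = file.path(outdir, "structures.csv"),
             breakthrough = file.path(outdir, "breakthrough.csv"),
             summaries = file.path(outdir, "summaries.csv"),
             curated = file.path(outdir, "curated.csv"),
             audit = file.path(outdir, "curation_audit.csv"),
             bundle = file.path(outdir, "model_bundle.json"),
             predictions = file.path(outdir, "predictions.csv"),
             attributions = file.path(outdir, "attributions.csv"),
             importance = file.path(outdir, "importance.csv"),
             log = file.path(outdir, "run_log.txt"),
             config = file.path(outdir, "run_config.txt"))
  write_structures(structures, paths["structures"])
  write.csv(values, paths["breakthrough"], row.names = FALSE)
  write.csv(summaries, paths["summaries"], row.names = FALSE)
  write.csv(cur$summaries, paths["curated"], row.names = FALSE)
  write.csv(cur$audit, paths["audit"], row.names = FALSE)
  write_bundle(bundle, paths["bundle"])
  write.csv(preds, paths["predictions"], row.names = FALSE)
  write.csv(attribution_table(att, top_k = 20), paths["attributions"],
            row.names = FALSE)
  imp <- forest_importance(bundle$forest)
  write.csv(data.frame(feature = seq_along(imp),
                       name = names(imp) %||% paste0("bit", seq_along(imp)),
                       importance = unname(imp)),
            paths["importance"], row.names = FALSE)
  writeLines(lg, paths["log"])
  if (!is.null(cfg$config_source) && file.exists(cfg$config_source)) {
    file.copy(cfg$config_source, paths["config"], overwrite = TRUE)
  } else {
    writeLines(paste(names(cfg), "=",
                     vapply(cfg, function(x) paste(format(x), collapse = " "),
                            character(1))), paths["config"])
  }
  message(paste(lg, collapse = "\n"))
  invisible(list(structures = structures, values = values,
                 summaries = summaries, curated = cur,
                 fingerprints = fp, bundle = bundle, predictions = preds,
                 paths = paths))
}

#' Batch prediction for an arbitrary structure list
#'
#' Standardizes the given SMILES, featurizes them with the bundle's
#' descriptor kind, and returns bias-adjusted predictions with confidence
#' and similarity diagnostics. Invalid structures are reported with NA
#' predictions rather than dropped.
#'
#' @param bundle a `ww_bundle`.
#' @param smiles character vector of SMILES (or a data.frame with
#'   `substance_id` and `smiles` columns).
#' @param ruleset rule set when the bundle uses the EPFP descriptor.
#' @return data.frame: prediction columns from [predict.ww_bundle()] plus
#'   `smiles` and `valid`.
#' @export
predict_structures <- function(bundle, smiles, ruleset = NULL) {
  stopifnot(inherits(bundle, "ww_bundle"))
  df <- if (is.data.frame(smiles)) smiles else
    data.frame(substance_id = paste0("q", seq_along(smiles)),
               smiles = smiles, stringsAsFactors = FALSE)
  st <- standardize_structures(df$smiles, df$substance_id)
  kind <- bundle$descriptor_kind %||% "MACCS"
  if (identical(kind, "EPFP") && is.null(ruleset)) ruleset <- read_ruleset()
  fp <- compute_fingerprints(st, kind = kind, ruleset = ruleset)
  out <- predict(bundle, fingerprint_matrix(fp))
  out$smiles <- df$smiles
  out$valid <- st$valid
  out$raw_logB[!st$valid] <- NA_real_
  out$adjusted_logB[!st$valid] <- NA_real_
  out$B[!st$valid] <- NA_real_
  out$confidence[!st$valid] <- NA_real_
  out
}
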