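# ---- structure standardization and deduplication -------------------------

#' Standardize chemical structures to QSAR-ready form
#'
#' Applies a fixed standardization recipe to each input SMILES: keep the
#' largest organic fragment (stripping counterions and solvents), neutralize
#' charges where a trivial proton transfer suffices, and emit the canonical
#' SMILES plus a hash-style `structure_key` used for deduplication. The key
#' has InChIKey first-block semantics: it ignores stereochemistry, so
#' stereoisomers share a key and are merged downstream (the fingerprints used
#' for modeling are stereo-insensitive). Inputs that do not parse, contain no
#' organic fragment, or remain multi-fragment mixtures after salt stripping
#' are returned with `valid = FALSE` and a reason -- never an exception.
#'
#' @param smiles character vector of input SMILES strings.
#' @param substance_id optional identifiers (default `s1`, `s2`, ...).
#' @return data.frame with columns `substance_id`, `smiles_input`,
#'   `smiles_canonical`, `structure_key`, `valid` (logical), `reason`.
#' @examples
#' \dontrun{
#' standardize_structures(c("CCO", "CCO.[Na+].[Cl-]", "C1CC"))
#' }
#' @export
standardize_structures <- function(smiles, substance_id = NULL) {
  stopifnot(is.character(smiles), length(smiles) >= 1L, all(nzchar(smiles)))
  if (is.null(substance_id)) substance_id <- paste0("s", seq_along(smiles))
  stopifnot(length(substance_id) == length(smiles),
            !anyDuplicated(substance_id))
  out <- chemtool_run("standardize", substance_id, smiles)
  res <- data.frame(substance_id = as.character(substance_id),
                    smiles_input = as.character(smiles),
                    smiles_canonical = out$smiles_canonical,
                    structure_key = out$structure_key,
                    valid = out$valid == 1L,
                    reason = out$reason,
                    stringsAsFactors = FALSE)
  n_bad <- sum(!res$valid)
  if (n_bad > 0) {
    message("standardize_structures: ", n_bad, "/", nrow(res),
            " structures flagged invalid")
  }
  res
}

#' Standardize a single SMILES string
#'
#' Convenience wrapper around [standardize_structures()] for one structure.
#' @param smiles_input a single SMILES string.
#' @return one-row data.frame as in [standardize_structures()].
#' @export
standardize_structure <- function(smiles_input) {
  stopifnot(is.character(smiles_input), length(smiles_input) == 1L)
  standardize_structures(smiles_input, substance_id = "s1")
}

#' Merge substances that share a structure key
#'
#' Substances whose standardized structures have the same `structure_key` are
#' treated as one substance everywhere downstream. The first id (in input
#' order) of each key group becomes the canonical id; monitoring records are
#' re-keyed accordingly. The total number of monitoring records never
#' changes, only their `substance_id` values.
#'
#' @param structures data.frame from [standardize_structures()].
#' @param records monitoring records data.frame with a `substance_id` column
#'   (see [read_monitoring()] for the schema).
#' @return list with elements `structures` (one row per retained substance),
#'   `records` (re-keyed), `id_map` (old id -> new id) and `n_merged`
#'   (number of substances absorbed into another id).
#' @export
deduplicate_substances <- function(structures, records) {
  stopifnot(is.data.frame(structures),
            all(c("substance_id", "structure_key", "valid") %in%
                  names(structures)))
  dangling <- setdiff(unique(records$substance_id), structures$substance_id)
  if (length(dangling) > 0) {
    stop("monitoring records reference unknown substance_id(s): ",
         paste(dangling, collapse = ", "), call. = FALSE)
  }
  # invalid structures have no key; they never merge
  key <- ifelse(structures$valid, structures$structure_key,
                paste0("INVALID::", structures$substance_id))
  canonical <- structures$substance_id[!duplicated(key)]
  names(canonical) <- key[!duplicated(key)]
  id_map <- setNames(as.character(canonical[key]), structures$substance_id)
  keep <- structures[!duplicated(key), , drop = FALSE]
  rownames(keep) <- NULL
  rec <- records
  if (nrow(rec) > 0) {
    rec$substance_id <- unname(id_map[as.character(rec$substance_id)])
  }
  n_merged <- nrow(structures) - nrow(keep)
  if (n_merged > 0) {
    message("deduplicate_substances: merged ", n_merged,
            " duplicate substance id(s)")
  }
  list(structures = keep, records = rec, id_map = id_map,
       n_merged = n_merged)
}

#' Read structures from a CSV file
#'
#' Expects columns `substance_id` and `smiles`.
#' @param path CSV file path.
#' @return data.frame from [standardize_structures()].
#' @export
read_structures <- function(path) {
  if (!file.exists(path)) stop("structure file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("substance_id", "smiles") %in% names(df)))
  standardize_structures(df$smiles, df$substance_id)
}

#' Write standardized structures to CSV
#' @param structures data.frame from [standardize_structures()].
#' @param path output CSV path.
#' @export
write_structures <- function(structures, path) {
  write.csv(structures, path, row.names = FALSE)
  invisible(path)
}
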