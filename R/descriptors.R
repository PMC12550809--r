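# ---- molecular fingerprints ----------------------------------------------

fp_kinds <- c(MACCS = "maccs", ECFP = "ecfp", PATH_HASHED = "rdkit")

#' Read a biotransformation rule set
#'
#' Tab-separated file with columns `rule_id`, `smarts`, `description`; the
#' file order fixes the fingerprint bit order. Every SMARTS must compile
#' (checked against the chemistry backend) and rule ids must be unique.
#'
#' @param path rule TSV path; default is the rule set shipped with the
#'   package (~60 functional-group biotransformation triggers written for
#'   aerobic biodegradation; users reproducing a specific external rule
#'   system should point this at their own exported rule file).
#' @return data.frame of class `ww_ruleset`.
#' @export
read_ruleset <- function(path = default_ruleset_path()) {
  if (!file.exists(path)) stop("rule file not found: ", path)
  rules <- read.csv(path, sep = "\t", stringsAsFactors = FALSE,
                    quote = "", colClasses = "character")
  stopifnot(all(c("rule_id", "smarts", "description") %in% names(rules)))
  if (anyDuplicated(rules$rule_id)) stop("duplicate rule_id in rule file")
  chk <- chemtool_run("checkrules", extra = path)
  bad <- chk$rule_id[chk$compiles == 0]
  if (length(bad) > 0) {
    stop("SMARTS does not compile for rule(s): ", paste(bad, collapse = ", "))
  }
  class(rules) <- c("ww_ruleset", "data.frame")
  rules
}

#' @rdname read_ruleset
#' @export
default_ruleset_path <- function() {
  system.file("extdata", "biotransformation_rules.tsv", package = "wwbreak")
}

#' Compute a fingerprint matrix for standardized structures
#'
#' Four fingerprint families are supported:
#' \describe{
#'   \item{MACCS}{the 166 public structural keys;}
#'   \item{ECFP}{extended-connectivity (circular) fingerprint, radius 2,
#'     hashed to 2048 bits, binary;}
#'   \item{PATH_HASHED}{standard path-enumeration hashed fingerprint,
#'     2048 bits;}
#'   \item{EPFP}{biotransformation-rule fingerprint: bit j is 1 iff rule
#'     j's SMARTS pattern (an expert-curated functional-group trigger for
#'     enzymatic transformation) matches the molecule.}
#' }
#' Fingerprints are a pure function of the canonical SMILES. Invalid
#' structures get an all-zero row and are flagged, never dropped silently.
#'
#' @param structures data.frame from [standardize_structures()].
#' @param kind one of `"MACCS"`, `"ECFP"`, `"PATH_HASHED"`, `"EPFP"`.
#' @param ruleset a [read_ruleset()] object; required iff `kind = "EPFP"`.
#' @return object of class `ww_fingerprints`: list with `kind`,
#'   `substance_ids`, `bits` (substances x n_bits 0/1 integer matrix),
#'   `n_bits`, `invalid` (logical flags), and for EPFP the `rule_ids`.
#' @export
compute_fingerprints <- function(structures,
                                 kind = c("MACCS", "ECFP", "PATH_HASHED",
                                          "EPFP"),
                                 ruleset = NULL) {
  kind <- match.arg(kind)
  stopifnot(is.data.frame(structures),
            all(c("substance_id", "smiles_canonical", "valid") %in%
                  names(structures)))
  smiles <- ifelse(structures$valid, structures$smiles_canonical, "")
  ids <- structures$substance_id
  if (kind == "EPFP") {
    if (is.null(ruleset)) stop("EPFP requires a ruleset", call. = FALSE)
    stopifnot(inherits(ruleset, "ww_ruleset"))
    rf <- tempfile(fileext = ".tsv")
    on.exit(unlink(rf), add = TRUE)
    write.table(ruleset, rf, sep = "\t", row.names = FALSE, quote = FALSE)
    out <- chemtool_run("smarts", ids, smiles, extra = rf)
  } else {
    out <- chemtool_run("fingerprint", ids, smiles,
                        extra = fp_kinds[[kind]])
  }
  bits <- bitstrings_to_matrix(out$substance_id, out$bits)
  invalid <- out$valid == 0 | !structures$valid
  if (any(invalid)) {
    bits[invalid, ] <- 0L
    message("compute_fingerprints: ", sum(invalid),
            " invalid structure(s) encoded as all-zero rows")
  }
  structure(list(kind = kind,
                 substance_ids = ids,
                 bits = bits,
                 n_bits = ncol(bits),
                 invalid = invalid,
                 rule_ids = if (kind == "EPFP") ruleset$rule_id else NULL),
            class = "ww_fingerprints")
}

#' @export
print.ww_fingerprints <- function(x, ...) {
  cat("<ww_fingerprints> kind:", x$kind, "|", length(x$substance_ids),
      "substances x", x$n_bits, "bits;", sum(x$invalid), "invalid\n")
  invisible(x)
}

#' Extract the bit matrix of a fingerprint object
#' @param fp a `ww_fingerprints` object (plain matrices pass through).
#' @return integer matrix with substance ids as rownames.
#' @export
fingerprint_matrix <- function(fp) {
  if (is.matrix(fp)) return(fp)
  stopifnot(inherits(fp, "ww_fingerprints"))
  m <- fp$bits
  rownames(m) <- fp$substance_ids
  m
}

#' Count unique fingerprint rows and list collision groups
#'
#' Distinct molecules can share an identical bit pattern ("fingerprint
#' collision"), which makes them indistinguishable to any downstream model;
#' heavy collision loads explain why sparse rule-based fingerprints can
#' underperform denser structural keys.
#'
#' @param fp a `ww_fingerprints` object or binary matrix with rownames.
#' @return list with `n_unique` (distinct bit rows) and `collision_groups`
#'   (list of substance-id vectors sharing a row; groups of 1 omitted).
#' @export
count_unique_fingerprints <- function(fp) {
  m <- fingerprint_matrix(fp)
  if (nrow(m) == 0) stop("empty fingerprint matrix")
  key <- apply(m, 1, paste, collapse = "")
  groups <- split(rownames(m), key)
  list(n_unique = length(groups),
       collision_groups = unname(groups[lengths(groups) > 1]))
}

#' Write a fingerprint matrix as dense CSV
#' @param fp a `ww_fingerprints` object.
#' @param path output CSV path (first column `substance_id`).
#' @export
write_fingerprints <- function(fp, path) {
  m <- fingerprint_matrix(fp)
  colnames(m) <- if (!is.null(fp$rule_ids)) fp$rule_ids else
    paste0("bit", seq_len(ncol(m)))
  df <- data.frame(substance_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read an external numeric descriptor table (plug-in interface)
#'
#' Numeric descriptor backends (PaDEL/Mordred-style) are not computed
#' internally; their output is consumed as a CSV with a `substance_id`
#' column followed by numeric descriptor columns, and can be passed to the
#' modeling functions wherever a fingerprint matrix is accepted.
#' @param path CSV path.
#' @return numeric matrix with substance ids as rownames.
#' @export
read_descriptor_table <- function(path) {
  if (!file.exists(path)) stop("descriptor table not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  stopifnot("substance_id" %in% names(df))
  m <- as.matrix(df[setdiff(names(df), "substance_id")])
  if (!is.numeric(m)) stop("descriptor columns must be numeric")
  rownames(m) <- df$substance_id
  m
}
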