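#' @useDynLib wwbreak, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median sd var predict quantile coef lm optim rnorm runif
#'   setNames wilcox.test aggregate ave
#' @importFrom utils read.csv write.csv write.table head
"_PACKAGE"

# ---- RDKit command-line bridge -------------------------------------------
#
# No R cheminformatics toolkit is assumed; all structure-level primitives
# (SMILES parsing, canonicalization, InChIKey, fingerprints, SMARTS matching)
# are delegated to RDKit through `python`, one subprocess call per batch.
# The worker script ships with the package (inst/python/chemtool.py).

chem_python <- function() {
  py <- getOption("wwbreak.python", "")
  if (!nzchar(py)) py <- Sys.which("python")
  if (!nzchar(py)) py <- Sys.which("python3")
  if (!nzchar(py)) {
    stop("no `python` interpreter found on PATH; the chemistry backend ",
         "requires python with rdkit (set options(wwbreak.python=...))",
         call. = FALSE)
  }
  py
}

chemtool_script <- function() {
  p <- system.file("python", "chemtool.py", package = "wwbreak")
  if (!nzchar(p)) stop("chemtool.py not found in installed package")
  p
}

# Run one chemtool command over a substance_id/smiles table and read the
# resulting CSV back. `extra` holds trailing positional arguments.
chemtool_run <- function(cmd, ids = NULL, smiles = NULL, extra = character()) {
  fin <- tempfile(fileext = ".csv")
  fout <- tempfile(fileext = ".csv")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  args <- c(chemtool_script(), cmd)
  if (!is.null(ids)) {
    write.csv(data.frame(substance_id = as.character(ids),
                         smiles = as.character(smiles),
                         stringsAsFactors = FALSE),
              fin, row.names = FALSE, quote = TRUE)
    args <- c(args, fin)
  }
  args <- c(args, fout, extra)
  status <- suppressWarnings(
    system2(chem_python(), shQuote(args), stdout = TRUE, stderr = TRUE))
  code <- attr(status, "status")
  if (!is.null(code) && code != 0) {
    stop("chemistry backend failed (", cmd, "): ",
         paste(status, collapse = "\n"), call. = FALSE)
  }
  hdr <- names(read.csv(fout, nrows = 1))
  cc <- rep(NA_character_, length(hdr))
  names(cc) <- hdr
  cc[hdr %in% c("bits", "substance_id", "smiles_canonical",
                "structure_key", "reason", "rule_id")] <- "character"
  read.csv(fout, stringsAsFactors = FALSE, colClasses = cc)
}

# '0'/'1' strings -> binary integer matrix with substance_id rownames
bitstrings_to_matrix <- function(ids, bits) {
  if (length(bits) == 0L) return(matrix(0L, 0L, 0L))
  m <- do.call(rbind, lapply(strsplit(bits, ""), as.integer))
  rownames(m) <- ids
  m
}
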