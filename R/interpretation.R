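# ---- model interpretation: importance ranking and SHAP attributions ------

#' Feature importance across cross-validation folds
#'
#' Impurity-based importances (per-fold normalized to sum to 1) are
#' averaged over the fold models; the SD across folds measures ranking
#' stability. Either pass pre-trained fold ensembles or let the function
#' train one forest per outer fold.
#'
#' @param X,y training data (ignored when `forests` is given).
#' @param forests optional list of >= 2 `ww_forest` objects (one per fold).
#' @param n_folds,seed fold construction when training internally.
#' @param hyper forest hyperparameters for internal training.
#' @return data.frame sorted by mean importance: `feature` (index),
#'   `name`, `mean_importance`, `sd_importance`, `rank`; per-fold matrix in
#'   `attr(, "per_fold")`.
#' @export
cv_feature_importance <- function(X = NULL, y = NULL, forests = NULL,
                                  n_folds = 5, seed = 1, hyper = list()) {
  if (is.null(forests)) {
    X <- check_Xy(X, y)
    folds <- make_folds(nrow(X), n_folds, seed = seed)
    forests <- lapply(seq_len(n_folds), function(f) {
      set.seed(seed * 100 + f)
      fit_forest(X[folds != f, , drop = FALSE], y[folds != f],
                 n_trees = hyper$n_trees %||% 200,
                 max_depth = hyper$max_depth %||% Inf,
                 min_split = hyper$min_split %||% 2)
    })
  }
  stopifnot(length(forests) >= 2,
            all(vapply(forests, inherits, logical(1), "ww_forest")))
  imp <- vapply(forests, forest_importance,
                numeric(forests[[1]]$p))
  nm <- forests[[1]]$feature_names
  out <- data.frame(feature = seq_len(nrow(imp)),
                    name = if (is.null(nm)) paste0("bit", seq_len(nrow(imp)))
                           else nm,
                    mean_importance = rowMeans(imp),
                    sd_importance = apply(imp, 1, sd),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$mean_importance), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "per_fold") <- imp
  out
}

#' SHAP attributions for a trained bundle
#'
#' Exact path-dependent Shapley values of the tree ensemble (TreeSHAP),
#' averaged over trees, computed on the raw model and then rescaled by the
#' bias-correction line: attributions are multiplied by the slope and the
#' base value is mapped through the full affine correction, so local
#' accuracy holds on the adjusted scale -- for every row,
#' `base + sum(attributions)` equals the adjusted prediction -- and
#' attribution signs are preserved whenever the slope is positive.
#'
#' @param bundle a `ww_bundle` (the attribution is only defined for the
#'   tree ensemble; other model types error).
#' @param X rows to attribute; default the bundle's training matrix
#'   ("fitted values", the usual mechanistic-reading setting).
#' @return object of class `ww_attributions`: list with `phi` (rows x
#'   features, logB units), `base` (scalar expected prediction),
#'   `substance_ids`, `feature_names`.
#' @export
shap_attributions <- function(bundle, X = NULL) {
  if (!inherits(bundle, "ww_bundle") ||
      !inherits(bundle$forest, "ww_forest")) {
    stop("SHAP attribution is only defined for tree-ensemble bundles",
         call. = FALSE)
  }
  if (is.null(X)) X <- bundle$train_X
  X <- bundle_align(bundle, X)
  s <- forest_shap_raw(bundle$forest, X)
  slope <- bundle$bias$slope
  phi <- s$phi * slope
  base <- s$base * slope + bundle$bias$intercept
  ids <- rownames(X)
  if (is.null(ids)) ids <- paste0("q", seq_len(nrow(X)))
  nm <- bundle$forest$feature_names
  if (is.null(nm)) nm <- paste0("bit", seq_len(ncol(X)))
  colnames(phi) <- nm
  rownames(phi) <- ids
  structure(list(phi = phi, base = base, substance_ids = ids,
                 feature_names = nm, X = X),
            class = "ww_attributions")
}

#' @export
print.ww_attributions <- function(x, ...) {
  cat("<ww_attributions>", nrow(x$phi), "rows x", ncol(x$phi),
      "features; base =", signif(x$base, 4), "\n")
  invisible(x)
}

#' Long-format attribution table (beeswarm-style export)
#'
#' One row per (substance, feature) with the feature's presence flag, for
#' downstream summary plots of substructure effects.
#' @param attributions a `ww_attributions` object.
#' @param top_k keep only the `top_k` features by mean absolute
#'   attribution (`Inf` keeps all).
#' @return data.frame: `substance_id`, `feature`, `present`, `attribution`.
#' @export
attribution_table <- function(attributions, top_k = Inf) {
  stopifnot(inherits(attributions, "ww_attributions"))
  phi <- attributions$phi
  keep <- order(-colMeans(abs(phi)))[seq_len(min(top_k, ncol(phi)))]
  rows <- lapply(keep, function(j) {
    data.frame(substance_id = attributions$substance_ids,
               feature = attributions$feature_names[j],
               present = attributions$X[, j] != 0,
               attribution = phi[, j],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Retrain a bundle on the top-k most important features
#'
#' Ranks features by cross-validated impurity importance, keeps the best
#' `k`, and trains a new bundle restricted to that subset; the subset is
#' recorded so that `predict()` on full-width input auto-slices.
#'
#' @param X,y training data.
#' @param k number of features to retain (>= 1).
#' @param importance optional precomputed [cv_feature_importance()] table.
#' @param hyper,seed forwarded to [train_model()].
#' @return a `ww_bundle` with `feature_subset` set.
#' @export
retrain_on_top_features <- function(X, y, k, importance = NULL,
                                    hyper = list(), seed = 1) {
  Xm <- check_Xy(X, y)
  if (k < 1) stop("k must be >= 1")
  if (k > ncol(Xm)) stop("k exceeds the number of features")
  if (is.null(importance)) {
    importance <- cv_feature_importance(Xm, y, seed = seed)
  }
  subset <- sort(importance$feature[seq_len(k)])
  train_model(Xm, y, hyper = hyper, feature_subset = subset, seed = seed)
}

#' Catalog of notable MACCS key definitions
#'
#' Human-readable definitions for the 166 public structural keys used to
#' name substructures in interpretation outputs. A handful of keys central
#' to breakthrough interpretation (halogens, hydroxyl, rings, N-any-N,
#' heteroatom-CH2, large rings, terminal heteroatom-H) carry full text;
#' the remainder are labeled generically by index.
#'
#' @return data.frame: `key` (1-166), `definition`.
#' @export
maccs_key_catalog <- function() {
  def <- paste0("MACCS key ", 1:166)
  named <- c(
    "8"  = "ring of size >= 8 (QAAA@1, small-ring probe)",
    "77" = "N~*~N: two nitrogens separated by one atom, any bonds (matches imidazoles, guanidines)",
    "96" = "5-membered ring",
    "101" = "8-membered or larger ring (fused adjacent rings counted as one)",
    "125" = "more than one aromatic ring",
    "131" = "QH > 1: more than one heteroatom bearing hydrogen (terminal N-H/O-H groups)",
    "134" = "halogen present (-F, -Cl, -Br, -I)",
    "137" = "heterocycle",
    "138" = "Q~CH2~*: heteroatom bonded to a CH2 bonded to anything (e.g. tertiary-amine methylenes)",
    "139" = "hydroxyl group (-OH)",
    "144" = "*!@*~*!@*: non-ring linker pattern",
    "161" = "nitrogen present",
    "162" = "aromatic system present",
    "163" = "6-membered ring",
    "164" = "oxygen present",
    "165" = "ring present (aromatic or aliphatic)")
  idx <- as.integer(names(named))
  def[idx] <- paste0("MACCS key ", idx, ": ", unname(named))
  data.frame(key = 1:166, definition = def, stringsAsFactors = FALSE)
}
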