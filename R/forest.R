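# ---- random forest / tree-ensemble wrappers over the Rcpp CART core ------

as_feature_matrix <- function(X) {
  if (inherits(X, "ww_fingerprints")) X <- fingerprint_matrix(X)
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  X
}

#' Fit a forest of regression trees
#'
#' Greedy CART trees (variance-reduction splits) aggregated by averaging.
#' The three classic ensemble flavors are reachable through the switches:
#' random forest (`bootstrap = TRUE`, `mtry < p`), bagging (`bootstrap =
#' TRUE`, `mtry = p`) and extra-trees (`bootstrap = FALSE`, `random_split =
#' TRUE`). A single unbootstrapped tree (`n_trees = 1`, `bootstrap = FALSE`,
#' `mtry = p`) is the plain decision-tree regressor. All randomness flows
#' through R's RNG, so `set.seed()` makes fits bit-reproducible.
#'
#' @param X numeric feature matrix (or `ww_fingerprints`), rows = samples.
#' @param y numeric response (logB scale in this package).
#' @param n_trees number of trees.
#' @param mtry features considered per split; default `floor(sqrt(p))` when
#'   bootstrapping, else all.
#' @param max_depth maximum tree depth (`Inf` = unlimited).
#' @param min_split minimum node size to attempt a split.
#' @param min_leaf minimum samples per leaf.
#' @param bootstrap draw a bootstrap sample per tree.
#' @param random_split extra-trees style uniform random thresholds.
#' @param weights optional per-sample resampling probabilities (used by
#'   boosting wrappers).
#' @return object of class `ww_forest`.
#' @export
fit_forest <- function(X, y, n_trees = 300, mtry = NULL, max_depth = Inf,
                       min_split = 2, min_leaf = 1, bootstrap = TRUE,
                       random_split = FALSE, weights = NULL) {
  X <- as_feature_matrix(X)
  stopifnot(nrow(X) == length(y), all(is.finite(y)), n_trees >= 1)
  n <- nrow(X)
  p <- ncol(X)
  if (is.null(mtry)) mtry <- if (bootstrap) max(1L, floor(sqrt(p))) else p
  md <- if (is.finite(max_depth)) as.integer(max_depth) else -1L
  trees <- vector("list", n_trees)
  for (b in seq_len(n_trees)) {
    idx <- if (bootstrap) {
      sample.int(n, n, replace = TRUE, prob = weights)
    } else {
      seq_len(n)
    }
    trees[[b]] <- cpp_fit_tree(X, as.numeric(y), as.integer(idx - 1L),
                               as.integer(mtry), md, as.integer(min_split),
                               as.integer(min_leaf), random_split)
  }
  structure(list(trees = trees, p = p,
                 feature_names = colnames(X),
                 settings = list(n_trees = n_trees, mtry = mtry,
                                 max_depth = max_depth,
                                 min_split = min_split,
                                 min_leaf = min_leaf,
                                 bootstrap = bootstrap,
                                 random_split = random_split)),
            class = "ww_forest")
}

#' Predict from a fitted forest
#' @param object a `ww_forest`.
#' @param newdata feature matrix with the same columns as training.
#' @param per_tree return the n x n_trees matrix of per-tree predictions
#'   instead of their mean (needed for ensemble-variance confidence).
#' @param ... unused.
#' @export
predict.ww_forest <- function(object, newdata, per_tree = FALSE, ...) {
  X <- as_feature_matrix(newdata)
  if (ncol(X) != object$p) {
    stop("feature dimension mismatch: forest expects ", object$p,
         " columns, got ", ncol(X), call. = FALSE)
  }
  preds <- vapply(object$trees, function(tr) cpp_predict_tree(tr, X),
                  numeric(nrow(X)))
  if (nrow(X) == 1L) preds <- matrix(preds, nrow = 1L)
  if (per_tree) preds else rowMeans(preds)
}

#' Impurity-based feature importance of a forest
#'
#' Sum of SSE reductions at each feature's split nodes, averaged over trees
#' and normalized to sum to 1.
#' @param forest a `ww_forest`.
#' @return numeric vector of length p summing to 1 (all zero if no splits).
#' @export
forest_importance <- function(forest) {
  stopifnot(inherits(forest, "ww_forest"))
  imp <- numeric(forest$p)
  for (tr in forest$trees) {
    sp <- tr$feature >= 0
    if (any(sp)) {
      agg <- tapply(tr$gain[sp],
                    factor(tr$feature[sp] + 1L, levels = seq_len(forest$p)),
                    sum, default = 0)
      imp <- imp + as.numeric(agg)
    }
  }
  tot <- sum(imp)
  out <- if (tot > 0) imp / tot else imp
  if (!is.null(forest$feature_names)) names(out) <- forest$feature_names
  out
}

# per-tree SHAP averaged over the ensemble; returns list(phi, base)
forest_shap_raw <- function(forest, X) {
  X <- as_feature_matrix(X)
  stopifnot(ncol(X) == forest$p)
  phi <- matrix(0, nrow(X), forest$p)
  base <- 0
  for (tr in forest$trees) {
    s <- cpp_tree_shap(tr, X)
    phi <- phi + s$phi
    base <- base + s$base
  }
  k <- length(forest$trees)
  list(phi = phi / k, base = base / k)
}

#' @export
print.ww_forest <- function(x, ...) {
  s <- x$settings
  cat("<ww_forest>", s$n_trees, "trees, mtry", s$mtry, ", max_depth",
      s$max_depth, ", min_split", s$min_split, "\n")
  invisible(x)
}

#' Model factory for a default random forest
#'
#' Returns a `function(X, y)` fitting a random forest with the supplied
#' settings; used to inject a trained-model factory into
#' [criteria_sweep()] and similar harnesses.
#' @param ... arguments forwarded to [fit_forest()].
#' @export
forest_factory <- function(...) {
  args <- list(...)
  function(X, y) do.call(fit_forest, c(list(X = X, y = y), args))
}
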