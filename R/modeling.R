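# ---- benchmarking, optimization, bias correction, model bundle -----------

# SD of per-tree predictions per row; a single-tree ensemble has zero
# disagreement by definition (sd of one value would be NA)
per_tree_sd <- function(per_tree) {
  if (ncol(per_tree) == 1L) return(rep(0, nrow(per_tree)))
  apply(per_tree, 1, sd)
}

check_Xy <- function(X, y) {
  X <- as_feature_matrix(X)
  if (nrow(X) != length(y)) stop("X rows and y length differ")
  if (any(!is.finite(y))) {
    bad <- rownames(X)[!is.finite(y)]
    if (is.null(bad)) bad <- which(!is.finite(y))
    stop("non-finite target for substance(s): ",
         paste(head(bad, 10), collapse = ", "), call. = FALSE)
  }
  X
}

#' Benchmark regressor/descriptor pairs under nested cross-validation
#'
#' Outer 5-fold split estimates generalization; an inner cross-validation
#' on each outer training set selects hyperparameters from the learner's
#' grid, so the outer test fold never influences any modeling choice. The
#' outer split is fixed by `seed` and reused for every learner, making
#' per-fold scores paired across learners (required by [compare_models()]).
#'
#' @param X feature matrix or `ww_fingerprints` (rows aligned with `y`).
#' @param y numeric target (median logB per substance).
#' @param learners character vector of registry names (default: all 12).
#' @param registry learner registry, see [regressor_registry()].
#' @param n_outer,n_inner outer/inner fold counts.
#' @param seed integer; fixes fold assignment and all stochastic learners.
#' @return data.frame of class `ww_benchmark`, one row per learner x outer
#'   fold: `regressor`, `fold`, `R2`, `RMSE`, `params` (JSON), plus the
#'   fold assignment in `attr(, "folds")`.
#' @export
nested_cv_benchmark <- function(X, y, learners = NULL,
                                registry = regressor_registry(learners),
                                n_outer = 5, n_inner = 3, seed = 1) {
  X <- check_Xy(X, y)
  n <- nrow(X)
  if (n < n_outer) stop("fewer samples than outer folds")
  folds <- make_folds(n, n_outer, seed = seed)
  rows <- list()
  for (nm in names(registry)) {
    lr <- registry[[nm]]
    set.seed(seed + 1)  # stochastic learners start identically per fold run
    for (f in seq_len(n_outer)) {
      tr <- folds != f
      stopifnot(sum(tr) + sum(!tr) == n)
      params <- select_params(lr, X[tr, , drop = FALSE], y[tr], n_inner,
                              seed = seed + f)
      set.seed(seed * 1000 + f)
      fit <- lr$fit(X[tr, , drop = FALSE], y[tr], params)
      pred <- predict(fit, X[!tr, , drop = FALSE])
      rows[[length(rows) + 1]] <- data.frame(
        regressor = nm, fold = f,
        R2 = r_squared(y[!tr], pred),
        RMSE = rmse(y[!tr], pred),
        params = as.character(jsonlite::toJSON(params, auto_unbox = TRUE)),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "folds") <- folds
  attr(out, "seed") <- seed
  class(out) <- c("ww_benchmark", "data.frame")
  out
}

# inner-CV hyperparameter selection (lowest mean RMSE; first wins ties)
select_params <- function(learner, X, y, n_inner, seed) {
  grid <- learner$grid
  if (length(grid) == 1L) return(grid[[1]])
  folds <- make_folds(nrow(X), n_inner, seed = seed)
  scores <- vapply(grid, function(params) {
    errs <- vapply(seq_len(n_inner), function(f) {
      tr <- folds != f
      set.seed(seed * 131 + f)
      fit <- learner$fit(X[tr, , drop = FALSE], y[tr], params)
      rmse(y[!tr], predict(fit, X[!tr, , drop = FALSE]))
    }, numeric(1))
    mean(errs)
  }, numeric(1))
  grid[[which.min(scores)]]
}

#' Summarize a benchmark across folds
#' @param results a `ww_benchmark` data.frame.
#' @return data.frame with mean/median R2 and RMSE per regressor, sorted by
#'   mean R2 (best first).
#' @export
summarize_benchmark <- function(results) {
  stopifnot(inherits(results, "ww_benchmark") || is.data.frame(results))
  agg <- do.call(rbind, lapply(split(results, results$regressor),
                               function(d) data.frame(
    regressor = d$regressor[1],
    mean_R2 = mean(d$R2), median_R2 = median(d$R2),
    mean_RMSE = mean(d$RMSE), median_RMSE = median(d$RMSE),
    stringsAsFactors = FALSE)))
  agg <- agg[order(-agg$mean_R2), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' y-scrambling null distribution for the full modeling workflow
#'
#' Permutes the target, reruns the entire nested-CV workflow (including
#' hyperparameter selection) per repeat, and returns the null distribution
#' of mean R-squared together with the percentile of the unscrambled score
#' within it. A model whose unscrambled score does not clearly exceed the
#' null has learned nothing beyond chance correlation.
#'
#' @param X,y as in [nested_cv_benchmark()].
#' @param n_repeats number of label permutations.
#' @param seed integer seed (fold structure and permutations).
#' @param learners registry names to scramble (default `"rf"` to keep cost
#'   bounded; pass more for a full audit).
#' @param ... forwarded to [nested_cv_benchmark()].
#' @return list with `null_mean_R2` (numeric, length `n_repeats`),
#'   `unscrambled_mean_R2`, `percentile` of the unscrambled score in the
#'   null distribution.
#' @export
y_scramble <- function(X, y, n_repeats = 10, seed = 1, learners = "rf",
                       ...) {
  stopifnot(n_repeats >= 1)
  X <- check_Xy(X, y)
  real <- nested_cv_benchmark(X, y, learners = learners, seed = seed, ...)
  real_score <- mean(real$R2)
  null <- vapply(seq_len(n_repeats), function(r) {
    set.seed(seed * 7919 + r)
    yp <- sample(y)
    b <- nested_cv_benchmark(X, yp, learners = learners, seed = seed, ...)
    mean(b$R2)
  }, numeric(1))
  list(null_mean_R2 = null,
       unscrambled_mean_R2 = real_score,
       percentile = mean(null < real_score))
}

#' Pairwise model comparison on per-fold scores
#'
#' Paired Wilcoxon signed-rank tests on the per-fold R-squared values of
#' every regressor pair; valid because all regressors share the same outer
#' folds. Effects are reported as median per-fold differences (row minus
#' column); no multiplicity adjustment is applied beyond reporting.
#'
#' @param results a `ww_benchmark` data.frame.
#' @param metric `"R2"` (default) or `"RMSE"`.
#' @return data.frame: `regressor_a`, `regressor_b`, `median_diff`,
#'   `p_value`.
#' @export
compare_models <- function(results, metric = c("R2", "RMSE")) {
  metric <- match.arg(metric)
  by_reg <- split(results, results$regressor)
  folds_ok <- vapply(by_reg, function(d) paste(sort(d$fold), collapse = ","),
                     character(1))
  if (length(unique(folds_ok)) != 1) {
    stop("regressors were not evaluated on identical folds", call. = FALSE)
  }
  regs <- names(by_reg)
  rows <- list()
  for (a in regs) for (b in regs) {
    va <- by_reg[[a]][order(by_reg[[a]]$fold), metric]
    vb <- by_reg[[b]][order(by_reg[[b]]$fold), metric]
    d <- va - vb
    p <- if (all(d == 0)) 1 else
      suppressWarnings(wilcox.test(va, vb, paired = TRUE,
                                   exact = TRUE)$p.value)
    rows[[length(rows) + 1]] <- data.frame(
      regressor_a = a, regressor_b = b,
      median_diff = median(d), p_value = p, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# candidate ordering: better CV score first; among (rounded-)equal scores
# prefer simpler forests: fewer trees, then smaller depth, then LARGER
# minimum samples per split.
order_candidates <- function(score, n_trees, max_depth, min_split) {
  order(-round(score, 10), n_trees, max_depth, -min_split)
}

#' Optimize final forest hyperparameters
#'
#' Two-stage search as used for the final model: a randomized draw over
#' wide ranges followed by a local grid around the best random candidate.
#' Candidates are scored by k-fold CV R-squared; exact score ties are
#' broken toward simpler models with the precedence fewer trees, then
#' smaller depth, then larger minimum samples per split.
#'
#' @param X,y training data.
#' @param search list of ranges: `n_trees = c(lo, hi)`, `max_depth`,
#'   `min_split` (integer ranges), optionally `mtry` candidates.
#' @param n_random random candidates in stage one.
#' @param n_folds CV folds used for scoring.
#' @param seed integer seed.
#' @return list with `best` (the winning hyperparameter list), `trace`
#'   (data.frame of all evaluated candidates with CV scores).
#' @export
optimize_final <- function(X, y,
                           search = list(n_trees = c(50, 500),
                                         max_depth = c(3, 25),
                                         min_split = c(2, 20)),
                           n_random = 15, n_folds = 5, seed = 1) {
  X <- check_Xy(X, y)
  stopifnot(n_random >= 1)
  set.seed(seed)
  rint <- function(rg, k) sample(seq(rg[1], rg[2]), k, replace = TRUE)
  cand <- unique(data.frame(n_trees = rint(search$n_trees, n_random),
                            max_depth = rint(search$max_depth, n_random),
                            min_split = rint(search$min_split, n_random)))
  score_one <- function(nt, md, ms, fseed) {
    folds <- make_folds(nrow(X), n_folds, seed = fseed)
    mean(vapply(seq_len(n_folds), function(f) {
      tr <- folds != f
      set.seed(fseed * 100 + f)
      fo <- fit_forest(X[tr, , drop = FALSE], y[tr], n_trees = nt,
                       max_depth = md, min_split = ms)
      r_squared(y[!tr], predict(fo, X[!tr, , drop = FALSE]))
    }, numeric(1)))
  }
  eval_cands <- function(df) {
    df$score <- mapply(score_one, df$n_trees, df$max_depth, df$min_split,
                       MoreArgs = list(fseed = seed))
    df
  }
  stage1 <- eval_cands(cand)
  b1 <- stage1[order_candidates(stage1$score, stage1$n_trees,
                                stage1$max_depth, stage1$min_split)[1], ]
  local_grid <- expand.grid(
    n_trees = unique(pmax(search$n_trees[1],
                          pmin(search$n_trees[2],
                               b1$n_trees + c(-50, 0, 50)))),
    max_depth = unique(pmax(search$max_depth[1],
                            pmin(search$max_depth[2],
                                 b1$max_depth + c(-2, 0, 2)))),
    min_split = unique(pmax(search$min_split[1],
                            pmin(search$min_split[2],
                                 b1$min_split + c(-2, 0, 2)))))
  stage2 <- eval_cands(local_grid)
  all_cand <- rbind(cbind(stage1, stage = "random"),
                    cbind(stage2, stage = "grid"))
  best <- all_cand[order_candidates(all_cand$score, all_cand$n_trees,
                                    all_cand$max_depth,
                                    all_cand$min_split)[1], ]
  list(best = list(n_trees = best$n_trees, max_depth = best$max_depth,
                   min_split = best$min_split),
       trace = all_cand)
}

#' Fit the post-hoc bias-correction line
#'
#' Tree ensembles compress the prediction range (overestimate low, and
#' underestimate high values); an ordinary least squares fit of the
#' training targets on the raw training predictions yields an affine
#' correction `adjusted = slope * raw + intercept` that undoes the
#' compression. The line must be fitted on training data only.
#'
#' @param raw_train_predictions raw ensemble predictions on training data.
#' @param y_train training targets.
#' @return list with `slope` and `intercept`.
#' @export
fit_bias_correction <- function(raw_train_predictions, y_train) {
  r <- raw_train_predictions
  stopifnot(length(r) == length(y_train), length(r) >= 3,
            all(is.finite(r)), all(is.finite(y_train)))
  if (sd(r) == 0) {
    warning("constant raw predictions; using identity bias correction")
    return(list(slope = 1, intercept = mean(y_train) - mean(r)))
  }
  cf <- coef(lm(y_train ~ r))
  list(slope = unname(cf[2]), intercept = unname(cf[1]))
}

#' Train a prediction-ready model bundle
#'
#' Fits the tree ensemble on the full training set, the bias-correction
#' line on the training fit, stores the training fingerprints (for
#' similarity-based applicability checks) and the training distribution of
#' per-tree prediction SDs (for the percentile confidence score).
#'
#' @param X training features (`ww_fingerprints` or matrix); rownames are
#'   substance ids.
#' @param y training targets (median logB).
#' @param hyper list of forest hyperparameters (`n_trees`, `max_depth`,
#'   `min_split`, `mtry`), e.g. `optimize_final()$best`.
#' @param feature_subset optional integer indices of retained features (the
#'   bundle then expects -- or auto-slices to -- that subset).
#' @param descriptor_kind metadata tag, e.g. `"MACCS"`.
#' @param seed integer seed for the forest fit.
#' @param metadata free-form list stored in the bundle.
#' @return object of class `ww_bundle`.
#' @export
train_model <- function(X, y, hyper = list(), feature_subset = NULL,
                        descriptor_kind = NULL, seed = 1,
                        metadata = list()) {
  Xfull <- check_Xy(X, y)
  if (is.null(descriptor_kind) && inherits(X, "ww_fingerprints")) {
    descriptor_kind <- X$kind
  }
  Xm <- if (is.null(feature_subset)) Xfull else
    Xfull[, feature_subset, drop = FALSE]
  set.seed(seed)
  forest <- fit_forest(Xm, y,
                       n_trees = hyper$n_trees %||% 300,
                       mtry = hyper$mtry,
                       max_depth = hyper$max_depth %||% Inf,
                       min_split = hyper$min_split %||% 2)
  per_tree <- predict(forest, Xm, per_tree = TRUE)
  raw <- rowMeans(per_tree)
  bias <- fit_bias_correction(raw, y)
  tree_sd_train <- per_tree_sd(per_tree)
  structure(list(forest = forest,
                 bias = bias,
                 feature_subset = feature_subset,
                 n_features_full = ncol(Xfull),
                 train_X = Xm,
                 train_ids = rownames(Xfull),
                 train_y = y,
                 tree_sd_train = tree_sd_train,
                 target_stats = c(mean = mean(y), sd = sd(y)),
                 descriptor_kind = descriptor_kind,
                 seed = seed,
                 metadata = metadata),
            class = "ww_bundle")
}

# align new data with the bundle's feature space (auto-slice full-width
# input when the bundle was trained on a feature subset)
bundle_align <- function(bundle, X) {
  X <- as_feature_matrix(X)
  p_train <- ncol(bundle$train_X)
  if (ncol(X) == p_train) return(X)
  if (!is.null(bundle$feature_subset) &&
      ncol(X) == bundle$n_features_full) {
    return(X[, bundle$feature_subset, drop = FALSE])
  }
  stop("feature dimension mismatch: bundle expects ", p_train,
       if (!is.null(bundle$feature_subset))
         paste0(" (or full width ", bundle$n_features_full, ")"),
       " columns, got ", ncol(X), call. = FALSE)
}

#' Predict breakthrough with confidence and similarity metrics
#'
#' The bias-adjusted prediction is the primary output; the raw ensemble
#' mean, the per-tree SD (ensemble disagreement), Tanimoto similarity to
#' the training set and the percentile-based confidence score are attached
#' for applicability-domain assessment.
#'
#' @param object a `ww_bundle`.
#' @param newdata feature matrix (same descriptor kind and bit order as the
#'   bundle's training matrix).
#' @param ... unused.
#' @return data.frame: `substance_id`, `raw_logB`, `adjusted_logB`, `B`,
#'   `tree_sd`, `similarity_nearest`, `similarity_nearest5`, `confidence`.
#' @export
predict.ww_bundle <- function(object, newdata, ...) {
  X <- bundle_align(object, newdata)
  per_tree <- predict(object$forest, X, per_tree = TRUE)
  raw <- rowMeans(per_tree)
  adj <- object$bias$slope * raw + object$bias$intercept
  tsd <- per_tree_sd(per_tree)
  sim <- similarity_profile(X, object$train_X)
  ids <- rownames(X)
  if (is.null(ids)) ids <- paste0("q", seq_len(nrow(X)))
  data.frame(substance_id = ids,
             raw_logB = raw,
             adjusted_logB = adj,
             B = 10^adj,
             tree_sd = tsd,
             similarity_nearest = sim$similarity_nearest,
             similarity_nearest5 = sim$similarity_nearest5,
             confidence = confidence_score(tsd, object$tree_sd_train),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' @export
print.ww_bundle <- function(x, ...) {
  cat("<ww_bundle>", x$forest$settings$n_trees, "trees on",
      nrow(x$train_X), "substances x", ncol(x$train_X), "features (",
      x$descriptor_kind %||% "?", ")\n",
      " bias line: adjusted =", signif(x$bias$slope, 4), "* raw +",
      signif(x$bias$intercept, 4), "\n")
  invisible(x)
}

#' Serialize / restore a model bundle as a plain-text archive
#'
#' The bundle is written as a single JSON file (version-tagged) holding the
#' forest's node arrays, the bias line, training fingerprints and
#' calibration data, so no binary serialization format is required.
#' @param bundle a `ww_bundle`.
#' @param path output file (".json").
#' @export
write_bundle <- function(bundle, path) {
  obj <- list(format = "wwbreak-bundle", version = 1L,
              trees = bundle$forest$trees,
              forest_settings = bundle$forest$settings,
              p = bundle$forest$p,
              feature_names = bundle$forest$feature_names,
              bias = bundle$bias,
              feature_subset = bundle$feature_subset,
              n_features_full = bundle$n_features_full,
              train_X = bundle$train_X,
              train_ids = bundle$train_ids,
              train_y = bundle$train_y,
              tree_sd_train = bundle$tree_sd_train,
              target_stats = as.list(bundle$target_stats),
              descriptor_kind = bundle$descriptor_kind,
              seed = bundle$seed,
              metadata = bundle$metadata)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_bundle
#' @export
read_bundle <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "wwbreak-bundle")) {
    stop("not a wwbreak bundle: ", path)
  }
  # jsonlite may simplify the tree list to a data.frame of list columns
  trees <- if (is.data.frame(obj$trees)) {
    lapply(seq_len(nrow(obj$trees)), function(i)
      lapply(obj$trees, function(col) col[[i]]))
  } else obj$trees
  trees <- lapply(trees, function(tr) {
    tr$feature <- as.integer(tr$feature)
    tr$left <- as.integer(tr$left)
    tr$right <- as.integer(tr$right)
    tr
  })
  forest <- structure(list(trees = trees, p = obj$p,
                           feature_names = obj$feature_names,
                           settings = obj$forest_settings),
                      class = "ww_forest")
  train_X <- as.matrix(obj$train_X)
  rownames(train_X) <- obj$train_ids
  structure(list(forest = forest, bias = obj$bias,
                 feature_subset = obj$feature_subset,
                 n_features_full = obj$n_features_full,
                 train_X = train_X,
                 train_ids = obj$train_ids,
                 train_y = obj$train_y,
                 tree_sd_train = obj$tree_sd_train,
                 target_stats = unlist(obj$target_stats),
                 descriptor_kind = obj$descriptor_kind,
                 seed = obj$seed,
                 metadata = obj$metadata),
            class = "ww_bundle")
}
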