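# ---- applicability domain: similarity, ensemble variance, confidence -----

#' Tanimoto similarity of two bit vectors
#'
#' |a AND b| / |a OR b|. Two all-zero vectors have an undefined ratio; it
#' is returned as 0 with a warning (maximally dissimilar by convention).
#' @param a,b binary vectors of equal length.
#' @return similarity in [0, 1].
#' @export
tanimoto <- function(a, b) {
  if (length(a) != length(b)) stop("bit vectors differ in length")
  a <- as.logical(a); b <- as.logical(b)
  un <- sum(a | b)
  if (un == 0) {
    warning("both vectors all-zero; Tanimoto defined as 0")
    return(0)
  }
  sum(a & b) / un
}

# vectorized Tanimoto of every row of Q against every row of Tr
tanimoto_matrix <- function(Q, Tr) {
  Q <- as_feature_matrix(Q); Tr <- as_feature_matrix(Tr)
  stopifnot(ncol(Q) == ncol(Tr))
  inter <- tcrossprod(Q, Tr)                       # |a AND b|
  un <- outer(rowSums(Q), rowSums(Tr), "+") - inter  # |a OR b|
  s <- inter / un
  s[un == 0] <- 0
  s
}

#' Similarity profile of query structures against a training set
#'
#' For each query fingerprint, the Tanimoto similarity to the most similar
#' training molecule (`similarity_nearest`) and the mean similarity of the
#' five nearest (`similarity_nearest5`). With fewer than five training
#' molecules the mean runs over what exists and `nearest5_truncated` is
#' flagged.
#'
#' @param query fingerprint matrix (rows = queries) or single vector.
#' @param training training fingerprint matrix, non-empty.
#' @return data.frame: `similarity_nearest`, `similarity_nearest5`,
#'   attribute `nearest5_truncated`.
#' @export
similarity_profile <- function(query, training) {
  training <- as_feature_matrix(training)
  if (nrow(training) == 0) stop("empty training fingerprint matrix")
  if (is.null(dim(query))) query <- matrix(query, nrow = 1)
  s <- tanimoto_matrix(query, training)
  k <- min(5L, ncol(s))
  top5 <- apply(s, 1, function(r) mean(sort(r, decreasing = TRUE)[seq_len(k)]))
  out <- data.frame(similarity_nearest = apply(s, 1, max),
                    similarity_nearest5 = top5)
  attr(out, "nearest5_truncated") <- k < 5L
  out
}

#' Coverage-error curve under a confidence ranking
#'
#' Orders predictions by a reliability proxy and recomputes RMSE and
#' R-squared on progressively smaller retained subsets: fractions 100%,
#' 95%, ..., 10% in 5% steps. For similarity rankings the most similar
#' predictions are retained; for `tree_sd` the lowest-disagreement ones.
#' Ties at a cutoff keep all tied items, so the realized fraction can
#' slightly exceed the nominal one (both are reported).
#'
#' @param predictions data.frame from [predict.ww_bundle()] plus a `truth`
#'   column (observed median logB).
#' @param ranking `"similarity_nearest"`, `"similarity_nearest5"` or
#'   `"tree_sd"`.
#' @param value_col column holding the prediction (default
#'   `"adjusted_logB"`).
#' @return data.frame: `fraction` (nominal), `fraction_real`, `n`, `RMSE`,
#'   `R2`. The 100% row equals the global metrics exactly.
#' @export
coverage_curve <- function(predictions,
                           ranking = c("similarity_nearest",
                                       "similarity_nearest5", "tree_sd"),
                           value_col = "adjusted_logB") {
  ranking <- match.arg(ranking)
  stopifnot(is.data.frame(predictions),
            all(c("truth", value_col, ranking) %in% names(predictions)))
  if (nrow(predictions) < 20) stop("need >= 20 predictions for a curve")
  score <- predictions[[ranking]]
  # higher = more reliable for similarity; lower = more reliable for tree_sd
  if (ranking == "tree_sd") score <- -score
  fractions <- seq(1.0, 0.10, by = -0.05)
  n <- nrow(predictions)
  rows <- lapply(fractions, function(fr) {
    k <- ceiling(fr * n)
    cutoff <- sort(score, decreasing = TRUE)[k]
    keep <- score >= cutoff   # keep all tied items at the cutoff
    data.frame(fraction = fr,
               fraction_real = mean(keep),
               n = sum(keep),
               RMSE = rmse(predictions$truth[keep],
                           predictions[[value_col]][keep]),
               R2 = r_squared(predictions$truth[keep],
                              predictions[[value_col]][keep]))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Experimental-variability "ideal model" simulation
#'
#' Contextualizes achievable model performance: even a model that always
#' predicts within the observed between-plant variability cannot beat the
#' data's own noise. Per repeat, each substance's "prediction" is one of
#' its observed per-plant logB values drawn uniformly at random and scored
#' against the substance median; R-squared and RMSE are aggregated across
#' substances per repeat.
#'
#' @param values breakthrough values from [compute_breakthrough()].
#' @param n_repeats number of resampling repeats.
#' @param seed integer seed.
#' @param min_plants substances need at least this many plants (default 2).
#' @param method `"resample"` (draw an observed plant value) or
#'   `"gaussian"` (draw from Normal(median, observed SD)).
#' @return list with `R2` and `RMSE` vectors (per repeat), `mean_R2`,
#'   `median_RMSE`, `n_substances`.
#' @export
ideal_model_simulation <- function(values, n_repeats = 100, seed = 1,
                                   min_plants = 2,
                                   method = c("resample", "gaussian")) {
  method <- match.arg(method)
  set.seed(seed)
  per_plant <- aggregate(logB ~ substance_id + plant_id, data = values,
                         FUN = median)
  spl <- split(per_plant$logB, per_plant$substance_id)
  spl <- spl[lengths(spl) >= min_plants]
  if (length(spl) == 0) stop("no substances with >= ", min_plants, " plants")
  med <- vapply(spl, median, numeric(1))
  sds <- vapply(spl, sd, numeric(1))
  r2s <- rmses <- numeric(n_repeats)
  for (r in seq_len(n_repeats)) {
    pred <- if (method == "resample") {
      vapply(spl, function(v) v[sample.int(length(v), 1)], numeric(1))
    } else {
      rnorm(length(med), mean = med, sd = sds)
    }
    r2s[r] <- r_squared(med, pred)
    rmses[r] <- rmse(med, pred)
  }
  list(R2 = r2s, RMSE = rmses,
       mean_R2 = mean(r2s), median_RMSE = median(rmses),
       n_substances = length(spl))
}

#' Percentile-based confidence score from ensemble disagreement
#'
#' Maps a per-prediction tree SD to [0, 1] as one minus its mid-rank
#' percentile within the training distribution of tree SDs: confidence 1
#' means the trees agree more than on any training self-prediction,
#' confidence 0.5 sits at the training median, and a confidence below 0.4
#' means the disagreement is worse than for more than 60% of training
#' self-predictions. This calibration is an internal convention of this
#' package -- it is a relative, not a probabilistic, scale.
#'
#' @param tree_sd non-negative numeric vector of per-tree prediction SDs.
#' @param reference training distribution of tree SDs.
#' @return confidence values in [0, 1], monotone non-increasing in
#'   `tree_sd`.
#' @export
confidence_score <- function(tree_sd, reference) {
  stopifnot(all(tree_sd >= 0), length(reference) >= 1)
  n <- length(reference)
  vapply(tree_sd, function(s) {
    1 - (sum(reference < s) + 0.5 * sum(reference == s)) / n
  }, numeric(1))
}
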