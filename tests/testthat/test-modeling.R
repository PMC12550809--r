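planted_Xy <- function(n = 100, p = 15, seed = 5, noise = 0.2) {
  set.seed(seed)
  X <- matrix(rbinom(n * p, 1, 0.5), n, p)
  rownames(X) <- paste0("m", seq_len(n))
  y <- 0.8 * X[, 1] - 0.5 * X[, 2] + 0.3 * X[, 3] + rnorm(n, 0, noise)
  list(X = X, y = y)
}

test_that("nested CV keeps folds leak-free, paired, and deterministic", {
  d <- planted_Xy()
  b1 <- nested_cv_benchmark(d$X, d$y, learners = c("rf", "knn"), seed = 17)
  folds <- attr(b1, "folds")
  expect_equal(sort(unique(folds)), 1:5)
  for (f in 1:5) {
    expect_equal(length(intersect(which(folds == f), which(folds != f))), 0)
  }
  # identical outer folds for every learner, by construction + pairing check
  expect_equal(nrow(b1), 10)
  expect_setequal(b1$fold, rep(1:5, 2))
  # same seed reproduces scores bit-identically; different seed does not
  b2 <- nested_cv_benchmark(d$X, d$y, learners = c("rf", "knn"), seed = 17)
  expect_identical(b1$R2, b2$R2)
  expect_identical(attr(b1, "folds"), attr(b2, "folds"))
  b3 <- nested_cv_benchmark(d$X, d$y, learners = c("rf", "knn"), seed = 18)
  expect_false(identical(attr(b1, "folds"), attr(b3, "folds")))
})

test_that("non-finite targets are rejected with substance names", {
  d <- planted_Xy(n = 30)
  y <- d$y; y[c(3, 7)] <- NA
  expect_error(nested_cv_benchmark(d$X, y, learners = "knn"), "m3")
})

test_that("a planted signal is learned while constant targets are not", {
  d <- planted_Xy(n = 120, noise = 0.15)
  b <- nested_cv_benchmark(d$X, d$y, learners = "rf", seed = 2)
  expect_gt(mean(b$R2), 0.5)
  yc <- rep(1.5, nrow(d$X))
  bc <- nested_cv_benchmark(d$X, yc, learners = "knn", seed = 2)
  expect_true(all(is.na(bc$R2) | bc$R2 <= 0))
})

test_that("the full registry exposes twelve learner families", {
  reg <- regressor_registry()
  expect_length(reg, 12)
  expect_setequal(names(reg),
                  c("mlr", "ridge", "kernel_ridge", "sgd", "linear_svr",
                    "rf", "gbr", "adaboost", "dt", "mlp", "svr_rbf", "knn"))
  expect_error(regressor_registry("nope"), "unknown learner")
  # uniform contract on a small problem
  d <- planted_Xy(n = 60, p = 8)
  for (nm in names(reg)) {
    set.seed(1)
    fit <- reg[[nm]]$fit(d$X, d$y, reg[[nm]]$grid[[1]])
    pred <- predict(fit, d$X)
    expect_length(pred, nrow(d$X))
    expect_true(all(is.finite(pred)), info = nm)
  }
})

test_that("y-scrambling nulls out the planted signal", {
  d <- planted_Xy(n = 90, noise = 0.15)
  ys <- y_scramble(d$X, d$y, n_repeats = 4, seed = 3, learners = "knn")
  expect_lt(mean(ys$null_mean_R2), 0.05)
  expect_gt(ys$unscrambled_mean_R2, max(ys$null_mean_R2))
  expect_equal(ys$percentile, 1)
  # determinism of the permutation machinery
  ys2 <- y_scramble(d$X, d$y, n_repeats = 4, seed = 3, learners = "knn")
  expect_identical(ys$null_mean_R2, ys2$null_mean_R2)
})

test_that("hyperparameter ties break toward simpler forests", {
  # equal scores: fewer trees first, then smaller depth, then larger
  # min-split
  o <- wwbreak:::order_candidates(score = c(0.5, 0.5),
                                  n_trees = c(500, 100),
                                  max_depth = c(10, 10),
                                  min_split = c(2, 2))
  expect_equal(o[1], 2L)
  o2 <- wwbreak:::order_candidates(score = c(0.5, 0.5),
                                   n_trees = c(100, 100),
                                   max_depth = c(10, 10),
                                   min_split = c(2, 10))
  expect_equal(o2[1], 2L)
  o3 <- wwbreak:::order_candidates(score = c(0.5, 0.5, 0.6),
                                   n_trees = c(100, 100, 500),
                                   max_depth = c(5, 10, 10),
                                   min_split = c(2, 2, 2))
  expect_equal(o3[1], 3L)  # better score beats simplicity
  expect_equal(o3[2], 1L)  # then smaller depth
})

test_that("optimize_final returns an evaluated candidate and a trace", {
  d <- planted_Xy(n = 60, p = 8)
  opt <- optimize_final(d$X, d$y,
                        search = list(n_trees = c(20, 40),
                                      max_depth = c(3, 6),
                                      min_split = c(2, 6)),
                        n_random = 2, n_folds = 3, seed = 5)
  expect_true(all(c("n_trees", "max_depth", "min_split") %in%
                    names(opt$best)))
  expect_gte(nrow(opt$trace), 2)
  expect_true(all(is.finite(opt$trace$score)))
  # a single random candidate is returned when the grid degenerates
  opt1 <- optimize_final(d$X, d$y,
                         search = list(n_trees = c(25, 25),
                                       max_depth = c(4, 4),
                                       min_split = c(2, 2)),
                         n_random = 1, n_folds = 3, seed = 5)
  expect_equal(opt1$best, list(n_trees = 25, max_depth = 4, min_split = 2))
})

test_that("bias correction recovers closed forms", {
  set.seed(8)
  y <- rnorm(50)
  b1 <- fit_bias_correction(y, y)
  expect_equal(b1$slope, 1, tolerance = 1e-10)
  expect_equal(b1$intercept, 0, tolerance = 1e-10)
  b2 <- fit_bias_correction(0.5 * y, y)
  expect_equal(b2$slope, 2, tolerance = 1e-10)
  expect_equal(b2$intercept, 0, tolerance = 1e-10)
  expect_warning(b3 <- fit_bias_correction(rep(2, 10), y[1:10]), "constant")
  expect_equal(b3$slope, 1)
  expect_equal(b3$intercept, mean(y[1:10]) - 2)
})

test_that("bias correction decompresses a range-compressed forest", {
  # forests shrink extremes toward the mean; the adjusted training slope
  # against truth must sit closer to 1 than the raw slope
  set.seed(12)
  X <- matrix(rbinom(150 * 10, 1, 0.5), 150, 10)
  y <- X %*% c(1, -0.8, 0.6, -0.4, 0.3, rep(0, 5)) + rnorm(150, 0, 0.1)
  y <- drop(y)
  fo <- fit_forest(X, y, n_trees = 60, min_split = 10)
  raw <- predict(fo, X)
  bc <- fit_bias_correction(raw, y)
  adj <- bc$slope * raw + bc$intercept
  slope_raw <- coef(lm(raw ~ y))[2]
  slope_adj <- coef(lm(adj ~ y))[2]
  expect_gt(bc$slope, 1)  # compression implies slope > 1 to undo it
  expect_lt(abs(slope_adj - 1), abs(slope_raw - 1))
  # monotone affine map: ranking unchanged
  expect_equal(order(adj), order(raw))
})

test_that("bundles predict, auto-slice, and survive a round trip", {
  d <- planted_Xy(n = 80, p = 12)
  bundle <- train_model(d$X, d$y, hyper = list(n_trees = 40), seed = 4)
  preds <- predict(bundle, d$X)
  expect_named(preds, c("substance_id", "raw_logB", "adjusted_logB", "B",
                        "tree_sd", "similarity_nearest",
                        "similarity_nearest5", "confidence"))
  # training points of a deep forest: adjusted close to fitted values
  expect_gt(r_squared(d$y, preds$adjusted_logB), 0.8)
  expect_equal(preds$B, 10^preds$adjusted_logB)
  expect_error(predict(bundle, d$X[, 1:5]), "mismatch")

  # single-tree bundle: TreeSD identically zero
  b1 <- train_model(d$X, d$y, hyper = list(n_trees = 1), seed = 4)
  expect_true(all(predict(b1, d$X)$tree_sd == 0))

  # JSON round trip preserves predictions exactly
  tmp <- tempfile(fileext = ".json")
  write_bundle(bundle, tmp)
  back <- read_bundle(tmp)
  expect_equal(predict(back, d$X)$adjusted_logB, preds$adjusted_logB)
})

test_that("model comparison is paired, antisymmetric, and exact", {
  d <- planted_Xy(n = 80)
  b <- nested_cv_benchmark(d$X, d$y, learners = c("rf", "knn", "mlr"),
                           seed = 9)
  cm <- compare_models(b)
  self <- cm[cm$regressor_a == cm$regressor_b, ]
  expect_true(all(self$p_value == 1))
  expect_true(all(self$median_diff == 0))
  ab <- cm[cm$regressor_a == "rf" & cm$regressor_b == "knn", ]
  ba <- cm[cm$regressor_a == "knn" & cm$regressor_b == "rf", ]
  expect_equal(ab$median_diff, -ba$median_diff)
  expect_equal(ab$p_value, ba$p_value)
  # a regressor dominant on all five folds reaches the exact two-sided
  # signed-rank floor for n = 5: 2/32
  fake <- b[b$regressor %in% c("rf", "knn"), ]
  fake$R2[fake$regressor == "rf"] <-
    fake$R2[fake$regressor == "knn"] + 1 + 0.01 * (1:5)  # distinct diffs
  class(fake) <- class(b)
  cmf <- compare_models(fake)
  expect_equal(cmf$p_value[cmf$regressor_a == "rf" &
                             cmf$regressor_b == "knn"], 2 / 32)
  # mismatched folds are rejected
  broken <- b[-1, ]
  class(broken) <- class(b)
  expect_error(compare_models(broken), "identical folds")
})
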