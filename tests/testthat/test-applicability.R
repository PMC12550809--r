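test_that("tanimoto matches hand counts and handles edge cases", {
  expect_equal(tanimoto(c(1, 1, 0, 1), c(1, 1, 0, 1)), 1)
  expect_equal(tanimoto(c(1, 1, 0, 0), c(0, 0, 1, 1)), 0)
  expect_equal(tanimoto(c(1, 1, 0, 0), c(1, 0, 1, 0)), 1 / 3)
  expect_warning(z <- tanimoto(c(0, 0), c(0, 0)), "all-zero")
  expect_equal(z, 0)
  expect_error(tanimoto(c(1, 0), c(1, 0, 1)), "length")
})

test_that("vectorized similarity equals the brute-force double loop", {
  set.seed(14)
  Tr <- matrix(rbinom(20 * 64, 1, 0.3), 20, 64)
  Q <- matrix(rbinom(8 * 64, 1, 0.3), 8, 64)
  prof <- similarity_profile(Q, Tr)
  oracle <- brute_tanimoto_profile(Q, Tr)
  expect_equal(prof$similarity_nearest, unname(oracle[, "nearest"]))
  expect_equal(prof$similarity_nearest5, unname(oracle[, "nearest5"]))
})

test_that("similarity profile edge cases behave", {
  Tr <- matrix(rbinom(10 * 32, 1, 0.4), 10, 32)
  # query present in training -> nearest exactly 1
  prof <- similarity_profile(Tr[3, ], Tr)
  expect_equal(prof$similarity_nearest, 1)
  # single-molecule training set: nearest5 = nearest, flagged truncated
  p1 <- similarity_profile(Tr[1:2, ], Tr[5, , drop = FALSE])
  expect_equal(p1$similarity_nearest5, p1$similarity_nearest)
  expect_true(attr(p1, "nearest5_truncated"))
  expect_error(similarity_profile(Tr[1, ], Tr[0, , drop = FALSE]), "empty")
})

test_that("coverage curve reproduces global metrics at 100% retention", {
  set.seed(15)
  n <- 80
  preds <- data.frame(truth = rnorm(n), adjusted_logB = rnorm(n),
                      tree_sd = runif(n),
                      similarity_nearest = runif(n),
                      similarity_nearest5 = runif(n))
  cc <- coverage_curve(preds, ranking = "tree_sd")
  expect_equal(nrow(cc), 19)  # 100%..10% in 5% steps
  expect_equal(cc$fraction[1], 1)
  expect_identical(cc$RMSE[1], rmse(preds$truth, preds$adjusted_logB))
  expect_identical(cc$R2[1], r_squared(preds$truth, preds$adjusted_logB))
  expect_true(all(diff(cc$n) <= 0))
  expect_true(all(cc$fraction_real >= cc$fraction - 1e-12))
  expect_error(coverage_curve(preds[1:10, ], ranking = "tree_sd"),
               ">= 20")
})

test_that("tree-SD ranking tracks planted heteroscedastic noise", {
  # noisy group has 4x the residual SD; tree_sd is a noisy proxy for it
  set.seed(16)
  n <- 400
  noisy <- rbinom(n, 1, 0.5)
  truth <- rnorm(n)
  preds <- data.frame(
    truth = truth,
    adjusted_logB = truth + rnorm(n, 0, ifelse(noisy, 0.8, 0.2)),
    tree_sd = ifelse(noisy, 0.8, 0.2) * runif(n, 0.7, 1.3),
    similarity_nearest = runif(n), similarity_nearest5 = runif(n))
  cc <- coverage_curve(preds, ranking = "tree_sd")
  expect_lt(cc$RMSE[cc$fraction == 0.25], cc$RMSE[cc$fraction == 1])
})

test_that("ideal-model simulation hits exact limits", {
  # zero within-substance variability: perfect score every repeat
  v0 <- rbind(bval("a", "P1", -1), bval("a", "P2", -1),
              bval("b", "P1", 0.2), bval("b", "P2", 0.2),
              bval("c", "P1", -2), bval("c", "P2", -2))
  sim0 <- ideal_model_simulation(v0, n_repeats = 20, seed = 2)
  expect_true(all(sim0$R2 == 1))
  expect_true(all(sim0$RMSE == 0))
  expect_equal(sim0$n_substances, 3L)
})

test_that("two-substance toy matches the enumerated resampling expectation", {
  # A in {0,1} (median 0.5), B in {2,3} (median 2.5): every draw gives
  # |residual| = 0.5 for both, hence RMSE = 0.5 and R2 = 1 - 0.5/2 = 0.75
  v <- rbind(bval("A", "P1", 0), bval("A", "P2", 1),
             bval("B", "P1", 2), bval("B", "P2", 3))
  sim <- ideal_model_simulation(v, n_repeats = 25, seed = 9)
  expect_true(all(abs(sim$RMSE - 0.5) < 1e-12))
  expect_true(all(abs(sim$R2 - 0.75) < 1e-12))
})

test_that("more within-substance spread strictly lowers simulated R2", {
  mk <- function(spread) {
    do.call(rbind, lapply(1:25, function(i) {
      center <- (i - 13) / 6
      rbind(bval(paste0("s", i), "P1", center - spread),
            bval(paste0("s", i), "P2", center),
            bval(paste0("s", i), "P3", center + spread))
    }))
  }
  lo <- ideal_model_simulation(mk(0.1), n_repeats = 40, seed = 4)
  hi <- ideal_model_simulation(mk(0.6), n_repeats = 40, seed = 4)
  expect_gt(lo$mean_R2, hi$mean_R2)
  # order invariance and reproducibility
  v <- mk(0.3)
  s1 <- ideal_model_simulation(v, n_repeats = 10, seed = 5)
  s2 <- ideal_model_simulation(v[rev(seq_len(nrow(v))), ],
                               n_repeats = 10, seed = 5)
  expect_equal(s1$R2, s2$R2)
})

test_that("confidence is the inverse percentile of tree SD", {
  ref <- c(0.1, 0.2, 0.3, 0.4, 0.5)
  expect_equal(confidence_score(0, ref), 1)
  expect_equal(confidence_score(0.3, ref), 0.5)  # training median
  expect_equal(confidence_score(10, ref), 0)
  x <- sort(runif(20))
  conf <- confidence_score(x, ref)
  expect_true(all(diff(conf) <= 0))
  expect_true(all(conf >= 0 & conf <= 1))
})
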