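test_that("breakthrough follows the effluent/influent ratio exactly", {
  r <- rbind(rec("a", "P1", cin = 10, ceff = 10),
             rec("a", "P2", cin = 10, ceff = 1),
             rec("a", "P3", cin = 4, ceff = 2))
  v <- compute_breakthrough(r)
  expect_equal(v$B, c(1, 0.1, 0.5))
  expect_equal(v$logB, c(0, -1, log10(0.5)))
  # round trip to machine precision
  expect_equal(10^v$logB, v$B)
})

test_that("LOQ handling: influent-censored rejected, effluent kept+flagged", {
  r <- rbind(rec("a", "P1", cin = 10, ceff = 5, inf_loq = TRUE),
             rec("a", "P2", cin = 10, ceff = 5, eff_loq = TRUE),
             rec("a", "P3", cin = 10, ceff = 0))
  v <- compute_breakthrough(r)
  expect_equal(nrow(v), 1)
  expect_true(v$effluent_below_loq)
  expect_equal(v$B, 0.5)
  rej <- attr(v, "rejected")
  expect_equal(nrow(rej), 2)
  expect_setequal(rej$reason, c("influent below LOQ", "zero effluent"))
  # optional floor keeps the zero-effluent record
  v2 <- compute_breakthrough(r, zero_effluent_floor = 0.05)
  expect_equal(nrow(v2), 2)
  expect_equal(min(v2$B), 0.005)
})

test_that("monitoring invariants are enforced", {
  expect_error(compute_breakthrough(rec("a", "P1", cin = 0, ceff = 1)),
               "c_influent")
  expect_error(compute_breakthrough(rec("a", "P1", cin = 1, ceff = -1)),
               "c_effluent")
})

test_that("substance summary takes the median across plants", {
  v <- rbind(bval("a", "P1", -1), bval("a", "P2", 0), bval("a", "P3", -2))
  s <- summarize_substances(v)
  expect_equal(s$median_logB, -1)
  expect_equal(s$n_plants, 3L)
  # single plant: median is that value, SD is missing
  s1 <- summarize_substances(bval("b", "P1", -0.5))
  expect_equal(s1$median_logB, -0.5)
  expect_true(is.na(s1$sd_logB))
})

test_that("two-stage aggregation matches the hand-computed fixture", {
  # 3 plants x 2 replicates: per-plant medians -0.8, 0.1, -1.5
  v <- rbind(bval("a", "P1", -1.0), bval("a", "P1", -0.6),
             bval("a", "P2", 0.2), bval("a", "P2", 0.0),
             bval("a", "P3", -2.0), bval("a", "P3", -1.0))
  s <- summarize_substances(v, per_plant = TRUE)
  expect_equal(s$median_logB, -0.8)
  expect_equal(s$sd_logB, sd(c(-0.8, 0.1, -1.5)))
  expect_equal(s$max_B, 10^0.1)
  # flat median over all six records differs
  s_flat <- summarize_substances(v, per_plant = FALSE)
  expect_equal(s_flat$median_logB, median(c(-1, -0.6, 0.2, 0, -2, -1)))
})

test_that("summary is permutation invariant and filter only removes", {
  v <- rbind(bval("a", "P1", -1), bval("a", "P2", 0), bval("a", "P3", -2),
             bval("b", "P1", 0.1), bval("b", "P4", 0.3))
  s1 <- summarize_substances(v)
  s2 <- summarize_substances(v[sample.int(nrow(v)), ])
  expect_equal(s1, s2)
  sf <- summarize_substances(v, plant_filter = c("P1", "P2"))
  expect_true(all(sf$n_plants <= s1$n_plants[match(sf$substance_id,
                                                   s1$substance_id)]))
  # a retained plant's contribution is unchanged
  expect_equal(sf$median_logB[sf$substance_id == "b"], 0.1)
})

test_that("batch-effect components match a manual ANOVA decomposition", {
  # two substances x two datasets x three values, hand-built
  v <- rbind(bval("a", "P1", 0.0, ds = "D1"), bval("a", "P2", 0.2, ds = "D1"),
             bval("a", "P3", 0.4, ds = "D1"), bval("a", "P4", 0.5, ds = "D2"),
             bval("a", "P5", 0.7, ds = "D2"), bval("a", "P6", 0.9, ds = "D2"),
             bval("b", "P1", -2.0, ds = "D1"), bval("b", "P2", -1.8, ds = "D1"),
             bval("b", "P3", -1.6, ds = "D1"), bval("b", "P4", -1.5, ds = "D2"),
             bval("b", "P5", -1.3, ds = "D2"), bval("b", "P6", -1.1, ds = "D2"))
  rep_ <- batch_effect_check(v, min_per_dataset = 3)
  expect_equal(rep_$n_eligible, 2L)
  # manual one-way components for substance a by dataset:
  # group means 0.2 / 0.7, grand 0.45; MSB = 2*3*(0.25^2)/1 = 0.375
  # within SS = 0.04*4 = 0.16, MSW = 0.16/4 = 0.04; n0 = 3
  # between = (0.375 - 0.04)/3
  a_row <- rep_$per_substance[rep_$per_substance$substance_id == "a", ]
  expect_equal(a_row$between_dataset_var, (0.375 - 0.04) / 3)
  expect_equal(a_row$within_dataset_var, 0.04)
  # substances are far apart (approx -1.55 vs 0.45): substance component
  # dominates the dataset component
  expect_gt(rep_$var_between_substances, rep_$var_between_datasets)
})

test_that("identical per-substance dataset means give a null batch effect", {
  set.seed(5)
  v <- do.call(rbind, lapply(c("a", "b", "c"), function(id) {
    mu <- rnorm(1)
    do.call(rbind, lapply(c("D1", "D2"), function(ds) {
      do.call(rbind, lapply(1:4, function(i)
        bval(id, paste0(ds, "P", i), mu + c(-0.1, 0, 0.1, 0)[i], ds = ds)))
    }))
  }))
  rep_ <- batch_effect_check(v, min_per_dataset = 3)
  expect_lt(rep_$var_between_datasets, 1e-10)
})

test_that("synthetic offsets 10x below substance spread are detected as such", {
  w <- fix_world()
  rep_ <- batch_effect_check(w$values, min_per_dataset = 3)
  expect_gt(rep_$n_eligible, 0)
  expect_gt(rep_$var_between_substances, rep_$var_between_datasets)
})

test_that("no eligible substances yields an informative empty report", {
  v <- bval("a", "P1", 0)
  expect_message(rep_ <- batch_effect_check(v), "no eligible")
  expect_equal(rep_$n_eligible, 0L)
  expect_equal(nrow(rep_$per_substance), 0L)
})
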