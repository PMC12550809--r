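test_that("the 10-substance fixture yields the hand-enumerated outcome", {
  fx <- curation_fixture()
  res <- apply_criteria(fx$summaries, fx$values, curation_criteria(),
                        props = fx$props)
  expect_setequal(res$summaries$substance_id, c("s01", "s08", "s10"))
  reasons <- setNames(res$audit$reasons, res$audit$substance_id)
  expect_equal(unname(reasons[c("s02", "s03", "s04", "s05", "s06", "s07",
                                "s09")]),
               c("I", "II", "III", "IV", "V", "V", "III"))
  # every dropped substance carries at least one reason (partition)
  expect_true(all(nzchar(res$audit$reasons[!res$audit$kept])))
  expect_true(all(res$audit$reasons[res$audit$kept] == ""))
  # s10 was re-summarized without its censored entry
  expect_equal(res$summaries$n_plants[res$summaries$substance_id == "s10"], 3L)
})

test_that("individual criteria act as documented", {
  fx <- curation_fixture()
  only <- function(which) {
    cc <- curation_criteria(use_I = FALSE, use_II = FALSE, use_III = FALSE,
                            use_IV = FALSE, use_V = FALSE)
    cc[[paste0("use_", which)]] <- TRUE
    cc
  }
  # criterion I: fewer than three plants
  r1 <- apply_criteria(fx$summaries, fx$values, only("I"))
  expect_setequal(r1$audit$substance_id[!r1$audit$kept], "s02")
  # criterion II, any-plant reading drops s03; median reading keeps it
  r2 <- apply_criteria(fx$summaries, fx$values, only("II"))
  expect_setequal(r2$audit$substance_id[!r2$audit$kept], "s03")
  cc_med <- only("II"); cc_med$ii_scope <- "median"
  r2m <- apply_criteria(fx$summaries, fx$values, cc_med)
  expect_true(all(r2m$audit$kept))
  # criterion III keeps substances with missing SD (single plant)
  v3 <- rbind(fx$values, bval("s11", "P1", -0.2))
  r3 <- apply_criteria(summarize_substances(v3), v3, only("III"))
  expect_true(r3$audit$kept[r3$audit$substance_id == "s11"])
  # with IV off, s10's censored outlier entry stays in and fires III too
  expect_setequal(r3$audit$substance_id[!r3$audit$kept],
                  c("s04", "s09", "s10"))
  # criterion V: missing property row errors by default, droppable via config
  r5cfg <- only("V")
  expect_error(apply_criteria(fx$summaries, fx$values, r5cfg,
                              props = fx$props[-1, ]), "s01")
  r5cfg$v_missing <- "drop"
  r5 <- apply_criteria(fx$summaries, fx$values, r5cfg,
                       props = fx$props[-1, ])
  expect_setequal(r5$audit$substance_id[!r5$audit$kept],
                  c("s01", "s06", "s07"))
  # use_V without any property table is a hard error
  expect_error(apply_criteria(fx$summaries, fx$values, only("V")),
               "property table")
})

test_that("criterion III applies the threshold as keep-strictly-below", {
  s <- data.frame(substance_id = c("lo", "at", "hi"),
                  median_logB = c(-1, -1, -1), n_plants = c(3L, 3L, 3L),
                  sd_logB = c(0.699, 0.7, 0.701), max_B = c(1, 1, 1),
                  any_effluent_below_loq = FALSE, stringsAsFactors = FALSE)
  cc <- curation_criteria(use_I = FALSE, use_II = FALSE, use_IV = FALSE,
                          use_V = FALSE)
  r <- apply_criteria(s, bval("lo", "P1", -1), cc)
  expect_setequal(r$summaries$substance_id, "lo")
  expect_equal(r$audit$reasons[r$audit$substance_id == "at"], "III")
})

test_that("criteria sweep covers all combinations with sane monotonicity", {
  w <- fix_world()
  fp <- fix_maccs()
  sweep <- criteria_sweep(w$values, fp,
                          model_factory = forest_factory(n_trees = 15),
                          n_folds = 5, seed = 3,
                          plant_filter = w$nfilter)
  expect_equal(nrow(sweep), 16)  # no property table -> criterion V excluded
  none <- sweep$n_train[sweep$combination == "none"]
  all_on <- sweep$n_train[sweep$combination == "I+II+III+IV"]
  expect_gte(none, max(sweep$n_train, na.rm = TRUE))
  expect_lte(all_on, min(sweep$n_train, na.rm = TRUE))
  # adding a criterion to a fixed combination never enlarges training data
  for (crit in c("use_I", "use_II", "use_III", "use_IV")) {
    others <- setdiff(c("use_I", "use_II", "use_III", "use_IV"), crit)
    key <- do.call(paste, c(sweep[others], sep = "|"))
    for (k in unique(key)) {
      on <- sweep$n_train[key == k & sweep[[crit]]]
      off <- sweep$n_train[key == k & !sweep[[crit]]]
      expect_lte(on, off)
    }
  }
  expect_true(all(is.finite(sweep$mean_R2)))
})
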