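# shared fixtures, memoized so the chemistry subprocess runs once per suite

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# small synthetic world used across modules (60 substances, default noise)
fix_world <- function() {
  memo("world", {
    cfg <- generator_config(n_substances = 60, seed = 421)
    gen <- generate_structures(cfg)
    mon <- generate_monitoring(gen, cfg)
    values <- compute_breakthrough(mon$records)
    nplants <- mon$plant_meta$plant_id[mon$plant_meta$n_eliminating]
    list(cfg = cfg, gen = gen, mon = mon, values = values,
         nfilter = nplants,
         summaries = summarize_substances(values, plant_filter = nplants))
  })
}

fix_maccs <- function() {
  memo("maccs", compute_fingerprints(fix_world()$gen$structures, "MACCS"))
}

# hand-rolled monitoring record constructor
rec <- function(id, plant, ds = "D1", cin, ceff, inf_loq = FALSE,
                eff_loq = FALSE) {
  data.frame(substance_id = id, plant_id = plant, dataset_id = ds,
             c_influent = cin, c_effluent = ceff,
             influent_below_loq = inf_loq, effluent_below_loq = eff_loq,
             stringsAsFactors = FALSE)
}

# breakthrough value constructor (bypasses concentrations)
bval <- function(id, plant, logB, ds = "D1", eff_loq = FALSE) {
  data.frame(substance_id = id, plant_id = plant, dataset_id = ds,
             B = 10^logB, logB = logB, effluent_below_loq = eff_loq,
             stringsAsFactors = FALSE)
}

# hand-built 10-substance curation fixture with designed violations of each
# criterion I-V; expected outcome enumerated by hand (see test-curation.R)
curation_fixture <- function() {
  v <- rbind(
    # s01 clean: 3 plants, tight spread
    bval("s01", "P1", -1.0), bval("s01", "P2", -0.9), bval("s01", "P3", -1.1),
    # s02 only two plants -> I
    bval("s02", "P1", -1.0), bval("s02", "P2", -1.1),
    # s03 one plant exceeds B = 1.2 -> II (sd stays below 0.7)
    bval("s03", "P1", log10(1.3)), bval("s03", "P2", -0.5),
    bval("s03", "P3", -0.6),
    # s04 high across-plant variability (sd = 1.1) -> III
    bval("s04", "P1", -2.2), bval("s04", "P2", -0.8), bval("s04", "P3", 0.0),
    # s05 every entry effluent-below-LOQ -> IV removes the substance
    bval("s05", "P1", -1.0, eff_loq = TRUE),
    bval("s05", "P2", -1.2, eff_loq = TRUE),
    bval("s05", "P3", -0.8, eff_loq = TRUE),
    # s06 strongly sorbing (K_OC 5000 L/kg) -> V
    bval("s06", "P1", -1.0), bval("s06", "P2", -1.1), bval("s06", "P3", -0.9),
    # s07 volatile (H = 1e-4 atm m3/mol) -> V
    bval("s07", "P1", -0.3), bval("s07", "P2", -0.4), bval("s07", "P3", -0.2),
    # s08 clean, four plants
    bval("s08", "P1", 0.0), bval("s08", "P2", -0.1), bval("s08", "P3", 0.05),
    bval("s08", "P4", -0.05),
    # s09 sd 0.75, above the 0.7 cap -> III (max B stays at 1.0)
    bval("s09", "P1", -1.5), bval("s09", "P2", -0.75), bval("s09", "P3", 0.0),
    # s10 one censored entry among four plants; survives after IV
    bval("s10", "P1", -0.5), bval("s10", "P2", -0.55),
    bval("s10", "P3", -0.45), bval("s10", "P4", -2.5, eff_loq = TRUE))
  props <- data.frame(
    substance_id = sprintf("s%02d", 1:10),
    koc = c(100, 100, 100, 100, 100, 5000, 100, 100, 100, 100),
    henry = c(rep(1e-8, 6), 1e-4, 1e-8, 1e-8, 1e-8),
    stringsAsFactors = FALSE)
  list(values = v, summaries = summarize_substances(v), props = props)
}

# independent O(n^2) Tanimoto oracle
brute_tanimoto_profile <- function(Q, Tr) {
  t(apply(Q, 1, function(q) {
    sims <- apply(Tr, 1, function(t) {
      un <- sum(q | t)
      if (un == 0) 0 else sum(q & t) / un
    })
    k <- min(5, length(sims))
    c(nearest = max(sims),
      nearest5 = mean(sort(sims, decreasing = TRUE)[seq_len(k)]))
  }))
}

# brute-force path-dependent Shapley values for one tree (exponential in p;
# oracle for the TreeSHAP implementation)
brute_tree_shap <- function(tree, x) {
  p <- length(x)
  exp_f <- function(S) {
    rec <- function(j) {
      f <- tree$feature[j + 1]
      if (f < 0) return(tree$value[j + 1])
      if (f %in% S) {
        if (x[f + 1] <= tree$threshold[j + 1]) rec(tree$left[j + 1])
        else rec(tree$right[j + 1])
      } else {
        l <- tree$left[j + 1]; r <- tree$right[j + 1]
        (tree$cover[l + 1] * rec(l) + tree$cover[r + 1] * rec(r)) /
          tree$cover[j + 1]
      }
    }
    rec(0)
  }
  phi <- numeric(p)
  feats <- 0:(p - 1)
  for (i in feats) {
    others <- setdiff(feats, i)
    for (k in 0:length(others)) {
      combs <- if (k == 0) list(integer(0)) else
        utils::combn(others, k, simplify = FALSE)
      w <- factorial(k) * factorial(p - k - 1) / factorial(p)
      for (S in combs) phi[i + 1] <- phi[i + 1] +
          w * (exp_f(c(S, i)) - exp_f(S))
    }
  }
  phi
}
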