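---
title: "Modeling micropollutant breakthrough from molecular structure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling micropollutant breakthrough from molecular structure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The endpoint and its assumptions

`wwbreak` models the breakthrough of trace organic contaminants through
conventional activated-sludge treatment: `B = C_effluent / C_influent`,
the fraction of a substance surviving a plant, with `logB = log10(B)` as
the regression target. Working in log10 keeps the endpoint symmetric
around "one order of magnitude of removal" and matches the convention of
environmental-fate modeling; every RMSE and SD in this package is in
log10 units.

Three assumptions are baked into the data model:

1. **Unit consistency within a record.** Influent and effluent
   concentrations of one record must share a unit (they may be
   semiquantitative peak areas); breakthrough is a ratio, so the unit
   cancels. This cannot be validated from the data and is declared a
   caller responsibility.
2. **The plant median is the quantity of interest.** A substance's
   endpoint is the median of its per-plant logB values — a "typical plant"
   summary, not a plant-specific prediction. When a plant contributes
   replicates, we first take the median within the plant and then across
   plants (two-stage). A flat median across all records is available via
   `per_plant = FALSE`; the two-stage default prevents heavily sampled
   plants from dominating the endpoint.
3. **Homogeneous technology.** Plants with a nitrifying-denitrifying step
   (N-eliminating) behave systematically differently from C-only plants,
   so the modeling endpoint is computed on N-eliminating plants when plant
   metadata is available (`restrict_n_eliminating`, default on). No
   plant-specific operational parameters enter the model.

LOQ handling follows the measured-values-over-imputation principle:
records with influent below the limit of quantification are rejected (the
denominator is unreliable); effluent values below the LOQ are *used as
measured* and only flagged, with curation criterion IV available to drop
them. A zero effluent concentration has no defined logB and rejects the
record; a half-LOQ-style substitution floor exists
(`zero_effluent_floor`) but is off by default because imputation would
silently bias the low-breakthrough tail.

## Curation criteria

Five criteria with the following defaults (all switchable, thresholds
configurable):

| Criterion | Rule | Default | Rationale |
|---|---|---|---|
| I | ≥ `min_plants` plants | 3 | fewer plants are not representative |
| II | all plant-level B ≤ `max_B` | 1.2 | B > 120% suggests analytical error or in-plant formation |
| III | across-plant SD of logB < `max_sd_logB` | 0.7 | highly variable substances blur the structure–activity signal |
| IV | drop effluent-below-LOQ entries | — | uncertain values; entry-level, applied before I–III and V |
| V | K_OC ≤ 4000 L/kg and H ≤ 1e-5 atm·m³/mol | — | sorption/volatilization-dominated removal conflicts with a biodegradation model |

Three readings were genuinely open and are resolved as follows:

- **Criterion II scope.** "Breakthrough values exceeding 120%" is read as
  *any* plant-level value over the cap excluding the substance
  (`ii_scope = "any"`); the permissive median-based reading would keep
  substances with suspect measurements and is available as
  `ii_scope = "median"`.
- **Criterion III boundary.** The keep-rule is strict (`SD < 0.7` keeps),
  so an SD of exactly 0.7 drops.
- **Single-plant substances under III.** With one plant the SD is
  undefined; such substances are kept (missing SD is not high SD) —
  criterion I exists to handle them.

Property values for criterion V (K_OC, Henry constant) are consumed from a
user-supplied table; predicting them is out of scope, and the table's
`source` column records the producing tool/version as data provenance.

The criteria sweep (`criteria_sweep()`) evaluates every on/off
combination: the test pool is the curated set under *all* applicable
criteria (highest confidence), split into five disjoint folds used only
for testing; each combination trains on its own curated set minus the
fold. Id-set intersection between any training set and its test fold is
asserted empty inside the loop.

## The batch-effect check

Pooling campaigns into one endpoint is only defensible if substances vary
more than campaigns do. `batch_effect_check()` estimates one-way
method-of-moments variance components on the substances that have at least
`min_per_dataset` values in two or more campaigns: the between-substance
component from grouping by substance, and the between-campaign component
from grouping the substance-centered values by campaign. A mixed model
would be more efficient but needs distributional assumptions the
comparison does not; negative moment estimates truncate at zero.

## Descriptors

MACCS (166 public keys), ECFP (radius 2, 2048 bits, binary — hash
collisions are accepted, no count vectors) and hashed path fingerprints
are computed by RDKit through a batch subprocess bridge; fingerprints are
a pure function of the canonical SMILES. The biotransformation-rule
fingerprint sets bit *j* when rule *j*'s SMARTS matches the molecule —
"an enzyme could attack here". The shipped rule file
(`inst/extdata/biotransformation_rules.tsv`, ~60 rules) is this package's
own curation of common aerobic biodegradation triggers (alcohol/aldehyde
oxidation, ester/amide/carbamate hydrolysis, N-/O-dealkylation,
dehalogenation, nitro/azo reduction, ring oxidations, recalcitrance
markers such as CF3 and imidazole). It deliberately does **not**
redistribute any external rule system: rule licensing and version drift
must not block a build, and any external rule export in the same TSV
schema drops in via `read_ruleset(path)`. Collision counting
(`count_unique_fingerprints()`) exists precisely because sparse rule
fingerprints can map many molecules to the same bit pattern, erasing their
distinguishability.

Structure standardization is a fixed recipe — largest organic fragment,
charge neutralization by trivial proton transfer, canonical SMILES — with
a stereo-insensitive structure key (InChIKey first block) for
deduplication: the fingerprints above are stereo-blind, so stereoisomers
would be indistinguishable to the model anyway and are merged up front.
Multi-fragment mixtures that survive salt stripping are flagged invalid:
a per-structure breakthrough of a mixture is ill-defined. Tautomer
canonicalization and 3-D geometry are out of scope.

## Modeling choices

**Registry.** Twelve regressor families sit behind one fit/predict
contract. Because no general ML stack is assumed at runtime, the tree
ensembles (CART with variance-reduction splits, random forest, bagging,
extra-trees, gradient boosting, AdaBoost.R2), kNN, the single-hidden-layer
MLP and both SVR variants are implemented in the package (trees in Rcpp).
The two SVRs minimize a *huberized* epsilon-insensitive loss
(epsilon = 0.1, smoothing h = 0.01) with L-BFGS-B — the same model class
as a QP-based SVR, chosen because no quadratic-programming solver is
available; the smoothing makes the objective differentiable and the fit
deterministic. "SGD" is a seeded mini-batch squared-loss linear model with
L2 penalty. Ridge/lasso-style linear models use glmnet.

**Nested cross-validation.** The outer 5-fold split is drawn once from
the seed and reused for every learner, so per-fold scores are paired and
`compare_models()` may run paired Wilcoxon signed-rank tests (two-sided,
exact when untied; a learner against itself reports p = 1 by convention
since the zero-difference case has no distribution). The inner loop (3
folds) selects hyperparameters by mean RMSE; outer test folds never touch
any selection. y-scrambling reruns this entire workflow — including
hyperparameter selection — per label permutation.

**Hyperparameter search.** `optimize_final()` draws random integer
candidates from wide ranges, then refines with a local grid around the
best draw. Score ties (after rounding at 1e-10 to absorb floating-point
noise) break toward simpler forests in the fixed precedence *fewer trees,
then smaller depth, then larger minimum samples per split* — simpler
models overfit less and predict faster at equal measured skill.

**Bias correction.** Averaging trees compresses the prediction range
(low values over-, high values under-predicted). An OLS line of training
targets on raw training predictions (`adjusted = slope·raw + intercept`)
undoes the compression; it is fitted on training data only, and with a
positive slope it is a monotone affine map, so prediction rankings are
unchanged. Degenerate constant raw predictions fall back to an identity
slope with a mean-shift intercept, with a warning.

**Feature reduction.** `retrain_on_top_features()` keeps the top-k
features by cross-validated impurity importance; k is the caller's choice
(by inner CV if desired) since no canonical value exists. Bundles record
the subset and auto-slice full-width inputs at prediction time.

## Applicability domain and confidence

Per prediction the bundle reports Tanimoto similarity to the nearest and
the five nearest training molecules, the SD of the individual tree
predictions (TreeSD), and a confidence score. Two zero fingerprints have
an undefined Tanimoto ratio, defined here as 0 with a warning.

`coverage_curve()` recomputes RMSE/R² on retained subsets at fractions
100%, 95%, …, 10%. That is 19 points; the source convention this mirrors
counts "18 subsets from all data to the top 10% in 5% increments", an
off-by-one we resolve in favor of the arithmetic. Ties at a cutoff keep
all tied predictions (the realized fraction is reported alongside the
nominal one), and the 100% row reproduces the global metrics exactly — a
tested invariant.

The 0–1 **confidence score** is one minus the mid-rank percentile of a
prediction's TreeSD within the training distribution of TreeSDs: 1 means
the trees agree more than on any training self-prediction, 0.5 sits at
the training median. This percentile construction is an internal
convention of this package — the scale is relative, not probabilistic —
and is flagged as such wherever it surfaces.

The **ideal-model simulation** contextualizes attainable scores: per
repeat, each substance's "prediction" is one of its observed per-plant
logB values drawn uniformly, scored against the substance median. Even
this noise-matching oracle cannot reach R² = 1 when plants disagree. A
Gaussian variant (draw from Normal(median, observed SD)) is available via
`method = "gaussian"`; resampling is the default because it adds no
distributional assumption.

## Interpretation

SHAP attributions use the exact path-dependent TreeSHAP recursion
implemented in Rcpp and verified in the test suite against brute-force
Shapley enumeration over feature subsets on small trees (agreement to
1e-10). Attributions are computed on the raw ensemble and rescaled by the
bias slope (base value through the full affine map), so local accuracy —
base + sum of attributions = adjusted prediction — holds to 1e-6 of the
prediction scale on every row, and signs are preserved for positive
slopes. Whether to attribute before or after bias correction was an open
choice; attributing the raw model and rescaling keeps the tree-exact
computation while reporting on the scale users see.

## The synthetic world

The generator emulates the *structure* of multi-campaign monitoring data:
overlapping campaigns with plant partitions, per-record plant noise
(`plant_sd`, default 0.3 log10 units — a realistic between-plant spread
for biologically removed substances), campaign offsets
(`dataset_offset_sd` 0.1, deliberately an order of magnitude below the
substance spread so the batch-effect check has a true negative), LOQ
censoring of the lowest 5% of concentrations, 2% multiplicative effluent
spikes (×1.5–3) as criterion-II true positives, a +0.3 logB shift at
C-only plants, and a planted, fingerprint-visible signal: halogens
+0.5, hydroxyl −0.4, rings +0.2 logB around a −0.8 baseline, truncated at
+0.3. True logB is *deterministic* given the fragment flags, which makes
the generalization ceiling analytic: `generative_r2_ceiling()` computes
`1 − mean((median_obs − true)²)/var(median_obs)` from the ground truth.

What a green test does establish: every pipeline stage transforms data as
specified, the learners recover a planted signal up to the noise ceiling,
attributions recover planted effect signs, and confidence ranks errors on
heteroscedastic data. What it does not: real monitoring data have
correlated measurement errors, structure-dependent analytical bias,
non-additive structure effects and a far larger chemical space — absolute
performance numbers on synthetic data say nothing about performance on
field data.

## Numerical notes and degenerate inputs

- All randomness flows through R's RNG; a seed fixes fold assignments,
  bootstrap draws, mtry subsampling (inside the C++ tree fitter, via R's
  RNG) and generator output bit-identically.
- R² uses the evaluated subset's own mean in the denominator and is NA
  when the truth is constant (no variance to explain); tests treat NA as
  "not positive".
- CART splits maximize SSE reduction with a 1e-12 minimum gain; constant
  features can never split and receive importance 0. Importances are
  normalized per tree ensemble to sum to 1 (0 if no splits).
- The MLP initializes weights at N(0, 0.1²) from the caller's seed and
  fits with L-BFGS-B (maxit 200, decay 0.1 default).
- Bundle serialization is version-tagged JSON (node arrays, bias line,
  training fingerprints, calibration SDs) — plain text, no binary
  formats.

## Known limitations

- The chemistry layer requires a `python` with rdkit on PATH; there is no
  pure-R fallback for SMILES parsing or SMARTS matching.
- The rule fingerprint's bit count (and hence collision statistics)
  depends entirely on the rule file supplied; counts obtained with the
  shipped default are not comparable to other rule systems.
- Kernel methods (kernel ridge, RBF-SVR) materialize the full kernel
  matrix — fine for thousands of substances, not for hundreds of
  thousands.
- The confidence score is calibrated only against training
  self-predictions; it is a ranking device, not a coverage guarantee, and
  conformal approaches are explicitly out of scope.
- Flow normalization and hydraulic residence-time matching of
  influent/effluent samples are assumed done upstream by the monitoring
  campaigns.
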