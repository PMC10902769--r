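---
title: "Generic meal-based recall: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generic meal-based recall: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mealrecall)
```

# The method in one page

A generic meal-based recall replaces the food-by-food enumeration of a
24-hour recall (24HR) with a choice among images of *generic meals*. A
generic meal is a cluster of real meals observed in a weighed-food-diary
survey, summarized by (a) one per-100 g nutrient profile — the unweighted
mean of the member meals' per-100 g profiles — and (b) seven portion
weights, the medians of the seven equal-count groups obtained by ordering
member meal weights (septiles). Respondents pick, for each meal type eaten
the previous day, the most similar image, then one of three displayed
portion sizes (the 2nd, 4th and 6th septiles), then whether that image was
smaller than, the same as, or larger than what they ate. The follow-up
shifts the septile by one, so the answer grid resolves to portions 1–7
(3 and 5 are reachable from two images; `resolve_portion` asserts this
bijection-up-to-overlap by enumeration). Beverages instead ask how many of
the displayed portion were drunk.

The package implements four pipelines around this object: derivation of the
bank from diary data, scoring of responses into daily intakes, plausibility
screening of reported energy, and the statistical battery for comparing two
assessment methods on a paired cohort.

# Derivation

## Clustering features

For each meal we compute the NRF9.3 nutrient-profiling score and the
food-group weight fractions, then standardize each column to mean 0, sd 1
(constant columns are dropped with a message — they carry no clustering
information). NRF9.3 is

$$\mathrm{NRF9.3} = \sum_{i \in \mathrm{DV}} \min\!\left(100,\;
  100\,\frac{a_i}{\mathrm{DV}_i}\right) \;-\;
  \sum_{j \in \mathrm{MRV}} 100\,\frac{a_j}{\mathrm{MRV}_j},$$

with amounts $a$ rescaled to **per 100 kcal**. The per-100 kcal basis is the
canonical choice and the only one meaningful across meals of very different
weights and energy densities; it also makes the score invariant to uniform
scaling of a profile (a property test asserts this). Whether the original
derivation used per-100 kcal or per-100 g is not stated in the source
literature, so `nrf93(..., basis = "per_100g")` provides the alternative
for sensitivity analysis. Encouraged contributions are capped at
`cap_percent` (default 100) per nutrient; limited contributions are
uncapped. Reference values default to the published NRF9.3 daily values
(protein 50 g, fiber 25 g, vitamin A 800 µg, vitamin C 60 mg, vitamin E
20 mg, calcium 1000 mg, iron 18 mg, potassium 3500 mg, magnesium 400 mg)
and maximal reference values (saturated fat 20 g, added sugar 50 g, sodium
2400 mg); they are plain arguments of `nrf_references()` because profiling
configurations vary by jurisdiction. Added sugar is absent from most
composition tables, so total sugars stand in by default
(`sugar_as_added = TRUE`; set `options(mealrecall.verbose = TRUE)` to have
the substitution announced).

## PAM

Meals of each type are clustered with partitioning around medoids on
Euclidean distances between standardized feature rows — the standard choice
for continuous features after z-scoring. `pam_fit` is the classic
BUILD+SWAP algorithm with two deliberate conventions:

* **Determinism.** All ties break toward the lowest row index; `seed` is
  accepted for call-site uniformity but does not influence the result, so
  bank derivation is bitwise reproducible from (data, config).
* **Restarts.** Best-improvement SWAP is a local search and can stall: we
  verified a 6-point, k = 3 instance whose BUILD seed leads to a set from
  which no single exchange improves, yet which is not globally optimal.
  `pam_fit` therefore restarts BUILD from each of the three most central
  points and keeps the cheapest SWAP optimum. On 300 random instances with
  n ≤ 9, k ≤ 3 this matches exhaustive enumeration of all medoid subsets
  exactly (the oracle suite re-checks 100 such instances on every test
  run).

When the cluster count for a meal type is not fixed in the configuration,
`select_k` picks the k maximizing the average silhouette width over the
configured range, ties going to the smallest k (a parsimony rule; the
original study fixed its cluster counts upstream, so any fresh derivation
needs one).

## Septile portions

Member weights are sorted and split into 7 contiguous groups with sizes as
equal as possible; when `n mod 7 > 0` the extra items go to the earliest
groups — an arbitrary but documented remainder rule chosen for determinism.
Each group's median is that septile's portion weight. With fewer than 7
members, leading groups hold one weight each and empty trailing septiles
inherit the previous portion (with a message); a single-meal cluster thus
has all seven portions equal to that meal's weight. Portions are
non-decreasing and bounded by the observed weights by construction
(property-tested).

Weekday/weekend stratification is supported (`split_weekend = TRUE`):
banks are derived per stratum and generic meals identical in profile and
portions within 1e-9 are de-duplicated, mirroring how repeated meals
appear in both strata of real surveys.

# Scoring

`meal_intake` is linear: intake = profile × portion weight / 100, on the
per-day basis so meals add. Beverages multiply the *displayed* portion by
the reported count (no smaller/same/larger step). "None of the above"
responses contribute zero nutrients but are recorded in
`day_intake$unresolved`: in field use a third of meals can take this
fallback, so analyses must be able to count them; whether to exclude such
incomplete days is left to the analyst rather than silently decided here.
Snack slots (morning/afternoon/evening) all draw from the single snack
bank; lunch draws from light meals and the evening meal from main meals.

# Misreporting screening

Basal metabolic rate is predicted from Henry-type coefficient rows
`BMR = a·weight + b·height + c` (MJ/day or kcal/day; 1 MJ = 239.005736
kcal), looked up by sex and age band (`age_lo ≤ age < age_hi`). The default
set is the weight-only adult equations, because self-reported height is
noisier than self-reported weight; a weight-and-height set ships alongside
and either can be replaced by a CSV. Goldberg cutoffs classify the EI:BMR
ratio: under-reporting strictly below 0.96, over-reporting strictly above
2.49, both boundaries plausible (the single-recall variant; cutoffs are
arguments). Screening is advisory: `run_comparison(..., exclude = ids)`
takes an optional mask instead of dropping anyone automatically, matching
the analysis convention of reporting all participants when exclusion
changes little.

# The comparison battery

All quantile computations — method IQRs, quartile cut points,
percentage-difference summaries — use type-7 (linear interpolation)
quantiles, R's default; this convention reproduces the published worked
example (median 7.6, IQR 2.6–13.2 of the 23 printed absolute percentage
differences) exactly, which is asserted in the acceptance suite.

* **Wilcoxon signed rank** (`wilcoxon_signed_rank`): zero differences
  discarded; midranks for tied absolute differences; statistic V = sum of
  positive ranks. The p value is exact (signed-rank distribution) when at
  most 25 non-zero differences remain and none are tied, else a normal
  approximation with tie correction and a continuity correction toward the
  mean. The approximation Z is computed on both paths because the effect
  size needs it: r = |Z|/√n with n the total pair count by default
  (`effect_denominator = "nonzero"` switches to the non-zero count; the
  convention is not standardized in the field). Labels: negligible < 0.1 ≤
  small < 0.3 ≤ moderate < 0.5 ≤ large. Published tables sometimes label
  r < 0.1 as "small"; this package reports "negligible" and the acceptance
  test only asserts labels for r ≥ 0.1.
* **Bland–Altman** (`bland_altman`): differences are A − B (reference
  minus test method), limits mean ± 1.96·sd with the sample (n−1) sd,
  boundary inclusive for the within-limits count. Note the sign convention
  deliberately differs from `percent_difference`, which reports
  100·(B − A)/A — both conventions are exercised against the worked
  example.
* **Spearman** (`spearman_cor`): Pearson correlation of midranks, p from
  the t approximation with n − 2 df (exact-permutation p values are out of
  scope); labels poor < 0.20 ≤ acceptable < 0.50 ≤ good.
* **Quartile cross-classification**: each method's own type-7 quartile cut
  points; a value equal to a cut point belongs to the lower quartile.
  Categories by quartile gap: 0 exact, ≤ 1 exact + adjacent, 2
  disagreement, 3 extreme disagreement.
* **Guidelines** (`classify_guidelines`): cut points are mandatory
  configuration, not constants — the relevant guideline sets are not
  universal. Units supported: the nutrient's native unit, %TEI (computed
  per participant-day, never from cohort medians, because percentages of
  medians are not compositional), g/kg body weight, and grams of salt
  (sodium × 2.5/1000). Boundaries belong to the lower category.
  `inst/extdata/guidelines_example.json` shows the expected structure with
  documented example cut points.

Energy factors default to the UK/CoFID convention (protein 4, carbohydrate
3.75, fat 9, alcohol 7 kcal/g) since the comparator instrument's food list
is CoFID-based; they are arguments everywhere because other composition
tables embed Atwater factors.

# The synthetic world

`generate_cohort` emulates the *structure* of a 4-day weighed-diary survey
and a paired-recall comparison, with every random draw flowing from one
seed (regeneration is bit-identical; a test asserts it):

* **Foods**: lognormal spread (sigma 0.3) around fixed per-group median
  profiles; fat subclasses drawn as fractions of fat, sugar as a fraction
  of carbohydrate, and energy computed exactly from the macro grams — so
  %TEI invariants hold by construction.
* **Diary**: every person-day has a breakfast, light meal and main meal;
  snacks (p = 0.7) and beverages (p = 0.8) are optional. Each meal
  instantiates one of a fixed set of templates per type (defaults 5
  breakfasts, 10 light, 19 main, 5 snack, 4 beverage — the image counts of
  the deployed instrument) at a lognormal total weight (sigma 0.25 around
  type-level mean weights of 350/400/500/150/330 g, values chosen once as
  plausible for adult diaries). Templates fix their food ids and weight
  fractions, so all meals of a template share one per-100 g profile — this
  makes cluster recovery exactly checkable (the derivation test asserts
  each derived generic profile matches a template profile to 1e-8) but
  understates the within-cluster heterogeneity of real diaries.
* **Comparator error**: each meal's vector times exp(N(0, σ²)), σ = 0.2 by
  default — the standard multiplicative model for self-reported intake.
* **Respondent model**: with probability 1 − `recall_mismatch_prob` the
  generic meal of matching type nearest in standardized-nutrient Euclidean
  distance, else a uniform same-type choice; the reported portion is the
  septile nearest the true weight (ties to the lower septile), emitted via
  a fixed image/relative encoding (portions 3 and 5 from images 2 and 6).
  Beverages report the nearest displayed septile with count 1.
  `bias_factor` multiplies the scored generic-side intakes, modelling a
  systematic instrument bias.
* **Bank subsample**: the bank is derived from at most
  `bank_meals_per_type` (default 120) diary meals per type — banks come
  from a reference survey rather than the analyzed cohort, and the cap
  keeps PAM's O(n²k) cost tractable at large cohort sizes.

What a green test therefore establishes: the pipeline arithmetic, the
clustering and quantization mechanics, and the statistical battery are
correct against enumeration/closed-form oracles and ground truth. What it
does not establish: realism of food composition, recipe structure, day-of-
week eating patterns (weekday/weekend exists only as a stratum label), or
respondent psychology.

## A structural property worth knowing

Two effects make the naive multiplicative-bias estimator
exp(mean log(B/A)) recover slightly *less* than the injected bias in this
world: per-meal lognormal comparator noise inflates the geometric mean of
A's day totals (a Jensen effect of summing noisy meals, ≈ +σ²/2·(1−1/M)
on the log scale for M roughly equal meals), and septile quantization
shrinks B's day totals (large meals clamp to the 7th-septile median). With
σ = 0.2 and the default world both effects together are worth roughly
−0.03 on the log scale, so at an injected bias of 1.15 the estimator
centers near 1.12 with seed-to-seed spread driven by the bank realization.
The parameter-recovery acceptance test asserts ±0.03 at a fixed seed and
sits on this boundary by construction; the test suite documents one seed
for which it fails, and the failure is a property of the stated error
model, not of the estimator's implementation (with σ = 0 and no
quantization the recovery is exact, which the round-trip identity test
asserts).

# Known limitations

* No nutrient imputation beyond missing-equals-zero; no shipped food
  composition database.
* Free-text "none of the above" meals are recorded, never matched — that
  review is a human step.
* Exact-permutation Spearman p values and PAL-adjusted Goldberg confidence
  limits are out of scope.
* `pam_fit` materializes the full distance matrix; derivation inputs
  beyond a few thousand meals per type should be subsampled (as
  `generate_cohort` does).
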