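---
title: "Methods: DQQ diet quality indicators, design-based comparison, and the synthetic survey generator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: DQQ diet quality indicators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dqqkit)
```

# The measurement model

The Diet Quality Questionnaire (DQQ) records, for each respondent,
whether each of 29 food groups was consumed in the previous 24 hours.
All analysis in `dqqkit` starts from that 29-dimensional binary vector;
quantities, portions and within-group food identities are outside the
instrument. The taxonomy (codes, display labels, the 17 "promote" / 12
"limit" partition, and the canonical report order) lives in a single
machine-readable table, `inst/extdata/dqq_food_groups.tsv`, loaded at
runtime — the one source of truth for column names and row order.

Nine population-level indicators are computed per respondent
(`score_respondents()`). Each is a function of which *items* are hit,
where an item is a set of food groups scored "any consumed" with an
integer point weight (`indicator_membership()`):

* **FGDS** sums 10 items of weight 1 (range 0–10).
* **MDD-W** is FGDS ≥ 5, defined only for women aged 15–49; everyone
  else is *not applicable* (`NA`), never `FALSE`, so that prevalence
  denominators restrict correctly.
* **All-5** is the conjunction of five any-of components.
* **NCD-Protect** sums 9 singleton items of weight 1 (0–9).
* **NCD-Risk** sums 8 items with total weight 9: processed meat counts
  2; fast food + instant noodles share one item; the two unprocessed
  red meat groups share one item (0–9).
* **GDR** = NCD-Protect − NCD-Risk + 9 (0–18).
* **Zero fruit/vegetable**, **sweet beverage**, **unhealthy/UPF** are
  any-of flags over 6, 3 and 6 groups respectively.

Scores are kept integer-valued: the constructions are counts, and
integer arithmetic makes the exhaustive-enumeration checks exact.

## Membership conventions that were genuinely open

The published item lists do not enumerate every constituent food group,
so the following conventions are frozen here (they follow standard
MDD-W/DQQ practice) and, where debatable, exposed as switches:

* FGDS "grains/tubers" = grain staples ∪ whole grains ∪ roots/tubers;
  "dairy" = cheese ∪ yogurt ∪ milk; "meat/poultry/fish" = both
  unprocessed red meats ∪ processed meats ∪ poultry ∪ fish. Whether
  processed meat should count toward the FGDS meat item is not settled
  by the indicator's published definition; the default includes it
  (DQQ convention) and `fgds_processed_meat = FALSE` excludes it.
* FGDS "other vitamin-A rich fruits/vegetables" = vitamin A-rich orange
  vegetables ∪ vitamin A-rich fruits; "other fruits" absorbs citrus
  (the 10-item structure requires folding the DQQ's finer split).
* All-5 "animal-source foods" spans meat, fish, eggs and dairy groups.
* Fruit juice / fruit-flavoured drinks count as a *sweet beverage* and
  **not** as fruit: a juice-only respondent is simultaneously
  zero-fruit/vegetable and a sweet-beverage consumer.
* The sweet-beverage question wording "sweetened tea/milk/coffee"
  refers to sweetened milky drinks within that question; it does not
  pull the plain-milk food group into the indicator.
* The MDD-W age window `c(15, 49)` is a parameter of `mddw()` and
  `score_respondents()`, since some reports restrict adult
  denominators differently.

These choices imply two invariants the tests exploit: only 4 of the 10
FGDS items involve fruits or vegetables, so a zero-fruit/vegetable diet
has FGDS ≤ 6; and All-5 prevalence can never exceed any of its
sub-component prevalences.

# Design-based estimation and comparison

Respondents sampled within the same primary sampling unit are
correlated, which inflates the variance of estimated proportions (the
design effect). Descriptives follow the reporting convention of this
literature: weighted percentage with *unweighted* frequency for binary
indicators, median with interquartile range for scores. Weights default
to 1 — the analysis the package mirrors reports unweighted pooled
estimates — but every estimator accepts per-respondent weights.
Percentiles use linear interpolation between order statistics
(`quantile()` type 7), fixed so that the IQR is reproducible across
implementations.

## Cluster-adjusted Pearson chi-square

`cluster_adjusted_chi2()` tests independence of an outcome (R levels)
and a grouping factor (C levels). Let `p` be the vector of estimated
cell proportions. The uncorrected Pearson statistic is
`X² = n Σ (p_rc − p_r. p_.c)² / (p_r. p_.c)`. Its null distribution
under a cluster design is a weighted sum of χ²₁ variables whose
weights — the generalized design effects — are the eigenvalues of
`(H V₀ Hᵀ)⁻¹ (H V̂ Hᵀ)`, where `H` is the Jacobian of the
(R−1)(C−1) independence contrasts `h_rc = p_rc − p_r. p_.c`, `V₀` is
the multinomial covariance of `p` at sample size n, and `V̂` is the
design-based covariance estimated by Taylor linearization over
with-replacement cluster totals (clusters are the only design stage
modelled; no strata or finite-population corrections).

The default second-order (Satterthwaite) correction refers
`F = X² / (d λ̄)` to an F distribution with `d/(1+a²)` numerator and
`(K−1)·d/(1+a²)` denominator degrees of freedom, where `d` is the
contrast dimension, `λ̄` the mean eigenvalue, `a²` the squared
coefficient of variation of the eigenvalues and `K` the number of
clusters. The reported statistic is the corrected chi-square
`X²/(λ̄(1+a²))`. When the reference matrix is rank-deficient the
first-order correction (mean design effect via the trace) is used
instead, and the `correction` field records which was applied. Which
flavour the mirrored analysis used is not knowable from its report, so
the choice is a recorded switch rather than a hidden constant.

Two limiting behaviours pin the implementation down in the tests:
with one respondent per cluster and equal weights every eigenvalue is
`n/(n−1)`, so the corrected statistic equals the classical Pearson
chi-square times `(n−1)/n`; and on 2×2 tables the whole procedure
collapses to a scalar design effect, which an independently coded
direct formula reproduces to 6 decimals. Calibration is checked by
simulation: under a null with equal prevalences, intra-cluster
correlation 0.05 and 100 clusters of 10 (2000 replicates), the
rejection rate at α = 0.05 must fall in [0.03, 0.07]; under the
reference unhealthy/UPF contrast (76.8% vs 69.5%, a 9.5% minority
group, n = 5000, 400 replicates) power must reach 0.9. Degenerate
inputs are policy, not accidents: empty factor levels are dropped with
a warning, a single cluster is an error, and report rows whose outcome
has no variation carry an explicit `"-"` not-testable marker instead
of a test.

## Mann-Whitney U

Median comparisons use the plain (not cluster-adjusted) Mann–Whitney
U test — deliberately so, matching the analysis convention this
package mirrors; the limitation is recorded in the result's metadata
fields. When both samples have at most 8 observations the permutation
distribution of U is enumerated exactly, ties included; otherwise the
tie-corrected normal approximation is used *without* continuity
correction, so that it converges to the exact enumeration and matches
`wilcox.test(correct = FALSE)` in tie-free cases. Identical pooled
values yield p = 1 with a warning. U is invariant under strictly
monotone transforms of the pooled values, which the tests assert.

# The synthetic survey generator

`generate_population()` emulates the structure the estimators assume,
not any real country's diet:

* **Design.** Five countries totalling 5069 respondents; in-person
  countries are drawn as 100–125 clusters × 8–10 interviews (125×8,
  118×9, 125×8 by default), telephone countries as single-respondent
  clusters (no cluster stage). Cluster counts outside those bounds are
  rejected as infeasible.
* **Ages.** Adolescents (15–19, uniform) with share 9.5% by default;
  adult ages 20–79 follow a geometrically tapered pyramid
  (`exp(−(age−20)/25)`) — a one-time plausibility choice, since the
  mirrored design states only "15 and older".
* **Demographics.** Gender, education, residence and wealth quintile
  are drawn per age group from configurable margins (defaults from the
  reference sociodemographic distribution). Residence is drawn at
  respondent level to honour the per-age-group margins exactly, though
  real area samples make it a cluster attribute.
* **Consumption.** For each food group, each cluster draws
  `p_k ~ Beta(a, b)` with `a = p(1−ρ)/ρ`, `b = (1−p)(1−ρ)/ρ`, then
  respondents draw Bernoulli(`p_k`): marginal mean exactly `p`,
  within-cluster pairwise correlation exactly `ρ` (default ICC 0.05).
  Age-group-specific prevalences share one uniform per cluster mapped
  through each stratum's beta quantile function, so adolescents and
  adults in a cluster are positively correlated, as in an area sample.
  Per-age-group defaults come from
  `inst/extdata/default_prevalence.tsv`.
* **Cross-group dependence.** Food groups are independent given the
  cluster effect by default, which keeps derived indicators in closed
  form (e.g. unhealthy/UPF prevalence `1 − Π(1−p_g)` over its six
  groups under independence) — the basis of the generator-recovery
  tests. A single optional parameter (`healthfulness_sd`) adds a
  respondent-level latent factor that tilts promote-group log-odds up
  and limit-group log-odds down, inducing realistic positive
  within-category and negative cross-category correlation; it is off
  by default because no target correlation structure is available to
  calibrate it against, and the tilt slightly distorts marginal
  prevalences.
* **Determinism.** The seed lives in the config; draws are ordered by
  country, demographic field, then food group in canonical order, so
  the same config yields the identical table.

What the generator does **not** emulate: PPS selection from real
population frames, nonresponse, post-stratification weights, seasonal
or day-of-week effects, and — by default — any cross-food-group
correlation. Consequently, passing the pipeline's tests on synthetic
data validates the *machinery* (scoring arithmetic, design-corrected
inference, report assembly), not substantive dietary conclusions; in
particular the any-of indicators (All-5, sweet beverage, UPF) sit
higher under independence than they would with positively correlated
real diets, and no attempt is made to match published test statistics
computed on restricted real data.

# Numerical and validation choices

* **Exhaustive enumeration sizes.** Score ranges are verified over all
  2^19 patterns of the 19 groups entering NCD-Protect/NCD-Risk, all
  2^9 and 2^10 subsets for the protect/risk maxima, and — because FGDS
  depends on the diet only through which of its ten items are hit —
  all 2^10 patterns of one sentinel group per item for the FGDS range
  and the MDD-W threshold (minimum FGDS among positives = 5).
  `enumerate_diets()` refuses more than 2^22 patterns.
* **Simulation sizes.** Calibration uses 2000 null replicates and 400
  power replicates; generator recovery uses one draw of n = 50,000 at
  ICC 0 (1-percentage-point tolerance) and 120 clusters × 10 for ICC
  recovery (±0.03). These sizes make the checks' Monte-Carlo error
  small relative to their acceptance bands while keeping the default
  suite quick.
* **Validation policy.** `validate_diet()` accepts 0/1, logical,
  yes/no and true/false encodings; the lenient policy fills missing
  groups or values as not-consumed with one warning per column, the
  strict policy rejects, and unrecognized columns are always an error
  (so misspelt food-group columns cannot silently vanish).
  Round-tripping through the 0/1 CSV encoding is lossless.
* **Display.** Percentages render with 1 decimal and unweighted
  counts, medians as `median [q1-q3]`; p-values display as three
  decimals, floored at `p < 0.001`. Underlying table columns keep full
  precision; formatting never feeds back into computation.

# Known limitations

The Mann–Whitney comparison ignores clustering; the chi-square models
a single stage of clustering with replacement (no strata, no
finite-population correction, no multiple-testing adjustment — none is
applied in the reporting convention mirrored here). MDD-W from a
yes/no group recall tends to sit above questionnaire-based estimates
with fewer prompts, and the DQQ's lack of quantities means all
indicators are proxies, not adequacy measures. The synthetic
generator's independence default is a modelling convenience, not an
empirical claim about diets.
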