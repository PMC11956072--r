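# dqqkit

Population-level diet quality analysis for Diet Quality Questionnaire
(DQQ) surveys. The DQQ is a standardized 24-hour recall instrument that
asks yes/no consumption of 29 food groups; it is fielded in large
multistage cluster surveys to monitor what populations actually ate the
previous day. `dqqkit` is for analysts working with such data (or
planning such surveys): it scores the standard suite of nine diet
quality indicators per respondent, summarises and compares them with
statistics that respect the cluster design, and ships a synthetic
survey generator so the full pipeline can be exercised and validated
without access-restricted microdata.

## The indicators

For a consumption vector over the 29 food groups:

- **FGDS** — food group diversity score: the count of 10 aggregated food
  groups consumed (grains/tubers, pulses, nuts/seeds, dairy,
  meat/poultry/fish, eggs, dark green leafy vegetables, other vitamin
  A-rich fruits/vegetables, other vegetables, other fruits); range 0–10.
- **MDD-W** — minimum dietary diversity for women: FGDS ≥ 5, defined
  only for women of reproductive age (15–49 y); a proxy for
  micronutrient adequacy.
- **All-5** — consumed at least one starchy staple, vegetable, fruit,
  pulse/nut/seed and animal-source food (the five groups commonly
  recommended daily), plus the five sub-indicators.
- **NCD-Protect** — 0–9: one point per protective food group consumed
  (whole grains, pulses, nuts/seeds, 3 vegetable groups, 3 fruit
  groups).
- **NCD-Risk** — 0–9: weighted count over eight risk items — soft/energy
  drinks, baked sweets, other sweets, **processed meat (2 points)**,
  unprocessed red meat, deep-fried foods, fast food/instant noodles,
  salty snacks.
- **GDR score** = NCD-Protect − NCD-Risk + 9, range 0–18; higher means
  closer alignment with global dietary recommendations.
- **Zero fruit/vegetable**, **sweet beverage** and
  **unhealthy/ultra-processed food** consumption — binary any-of flags
  over their frozen food-group sets.

Estimation respects the survey design: proportions are compared with a
Rao–Scott cluster-adjusted Pearson χ² (second-order Satterthwaite
correction, F reference), medians with interquartile ranges are compared
by Mann–Whitney U (exact enumeration for small samples, tie-corrected
normal approximation otherwise).

## Worked example

```r
library(dqqkit)

pop    <- generate_population(default_scenario(seed = 1))
scores <- score_respondents(pop)
tab    <- build_indicator_table(pop, scores)
tab[tab$indicator %in% c("fgds", "all5", "gdr", "sweet_beverage",
                         "unhealthy_upf"),
    c("indicator", "cell_adolescent", "cell_adult", "comparison")]
#>   indicator      cell_adolescent cell_adult  comparison
#> 1 fgds           6 [5-7]         6 [5-7]     p = 0.248
#> 2 all5           37.4 (183)      39.7 (1820) chi2 (1, N = 5069) = 0.98, p = 0.322
#> 3 gdr            9 [8-11]        10 [9-12]   p < 0.001
#> 4 sweet_beverage 72.2 (353)      66.8 (3061) chi2 (1, N = 5069) = 5.9, p = 0.015
#> 5 unhealthy_upf  90.4 (442)      82.4 (3775) chi2 (1, N = 5069) = 20, p < 0.001
```

Each cell is `percent (unweighted count)` for proportions or
`median [q1-q3]` for scores; the comparison column reports the
cluster-adjusted χ² (with its corrected numerator df and the respondent
count) or the Mann–Whitney p-value across the two age groups
(adolescents 15–19 y vs adults 20+). Here the synthetic adolescents eat
more unhealthy/ultra-processed food and score lower on the GDR —
differences built into the generator's per-age-group prevalence
defaults.

Scoring a single respondent:

```r
d <- pop[3, ]
fgds(d); ncd_protect(d); ncd_risk(d); gdr(d)
#> 9; 6; 5; 10
mann_whitney_u(c(1, 2), c(3, 4))
#> mann_whitney = 0.0000, p = 0.333, n = 4 [none]
```

## The analysis workflow

Numbered drivers under `analysis/` run the whole study on synthetic
data and write their tables under `results/`:

```sh
Rscript analysis/01_simulate.R     # draw the 5-country, 5069-respondent survey
Rscript analysis/02_score.R       # per-respondent indicator scores
Rscript analysis/03_report.R      # sociodemographic / food-group / indicator tables
Rscript analysis/04_calibration.R # type-I error, power, generator recovery
```

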