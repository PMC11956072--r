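Package: dqqkit
Title: Diet Quality Indicators from DQQ 24-Hour Recall Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores the nine population-level diet quality indicators built on
    the Diet Quality Questionnaire (DQQ), a yes/no 24-hour recall over 29 food
    groups: food group diversity (FGDS), minimum dietary diversity for women
    (MDD-W), All-5, NCD-Protect, NCD-Risk, the Global Dietary Recommendations
    (GDR) score, zero fruit/vegetable, sweet beverage, and unhealthy/ultra-
    processed food consumption. Provides design-aware descriptive statistics
    and comparison tests for multistage cluster surveys (Rao-Scott corrected
    Pearson chi-square, Mann-Whitney U), report builders that summarise food
    group consumption and indicators by age group, gender or residence, and a
    synthetic multistage-survey data generator with configurable consumption
    prevalences and intra-cluster correlation for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
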