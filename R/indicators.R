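# Per-respondent diet quality indicators.
#
# All scoring functions are vectorised over the rows of a respondent table
# (or accept a single named diet vector) and are pure: survey weights play
# no role here, they enter only at estimation in the survey statistics.

# Internal: score one membership map over a diet matrix.
# Returns integer vector: sum over items of weight * any(constituent group).
.score_items <- function(m, membership) {
  items <- membership$items
  total <- integer(nrow(m))
  for (i in seq_len(nrow(items))) {
    cols <- items$groups[[i]]
    hit <- if (length(cols) == 1L) m[, cols] else rowSums(m[, cols, drop = FALSE]) > 0
    total <- total + items$weight[i] * as.integer(hit)
  }
  total
}

.any_group <- function(m, indicator_id) {
  cols <- unlist(indicator_membership(indicator_id)$items$groups)
  rowSums(m[, cols, drop = FALSE]) > 0
}

#' Food group diversity score (FGDS)
#'
#' Counts how many of ten aggregated food groups (grains/tubers,
#' pulses/legumes, nuts/seeds, dairy, meat/poultry/fish, eggs, dark green
#' leafy vegetables, other vitamin A-rich fruits/vegetables, other
#' vegetables, other fruits) were consumed in the previous 24 h. Range
#' 0-10; an aggregated group counts once if any constituent DQQ group was
#' consumed.
#'
#' @param diet A validated respondent table (see [validate_diet()]) or a
#'   named logical vector over [food_group_codes()].
#' @param fgds_processed_meat Passed to [indicator_membership()].
#' @return Integer vector in 0..10, one element per respondent.
#' @export
fgds <- function(diet, fgds_processed_meat = TRUE) {
  m <- .diet_matrix(diet)
  .score_items(m, indicator_membership("FGDS", fgds_processed_meat))
}

#' Minimum dietary diversity for women (MDD-W)
#'
#' `TRUE` when a woman of reproductive age reaches a food group diversity
#' score of at least 5. Respondents outside the eligible population
#' (males, or females outside the age window) get `NA` ("not applicable"),
#' never `FALSE`, so that prevalence denominators are restricted to
#' eligible women.
#'
#' @inheritParams fgds
#' @param age_years Integer vector of ages in completed years.
#' @param gender Character vector, `"female"` or `"male"`.
#' @param age_window Inclusive eligibility window in years; default the
#'   reproductive-age convention `c(15, 49)`.
#' @return Logical vector with `NA` for ineligible respondents.
#' @export
mddw <- function(diet, age_years, gender, age_window = c(15L, 49L),
                 fgds_processed_meat = TRUE) {
  score <- fgds(diet, fgds_processed_meat)
  eligible <- gender == "female" &
    age_years >= age_window[1] & age_years <= age_window[2]
  ifelse(eligible, score >= 5L, NA)
}

#' All-5: consumed all five recommended food groups
#'
#' The five food groups commonly recommended for daily consumption in
#' food-based dietary guidelines: at least one starchy staple, vegetable,
#' fruit, pulse/nut/seed, and animal-source food.
#'
#' @inheritParams fgds
#' @return A tibble with logical columns `all5` and the five components
#'   `all5_starchy_staple`, `all5_vegetable`, `all5_fruit`,
#'   `all5_pulse_nut_seed`, `all5_animal_source`. `all5` is the
#'   conjunction of the components.
#' @export
all5 <- function(diet) {
  m <- .diet_matrix(diet)
  items <- indicator_membership("ALL5")$items
  comp <- lapply(seq_len(nrow(items)), function(i) {
    rowSums(m[, items$groups[[i]], drop = FALSE]) > 0
  })
  names(comp) <- paste0("all5_", items$item)
  out <- tibble::as_tibble(comp)
  tibble::add_column(out, all5 = Reduce(`&`, comp), .before = 1L)
}

#' NCD-Protect score
#'
#' One point for each of nine food groups whose consumption marks dietary
#' behaviours protective against non-communicable diseases (whole grains,
#' pulses, nuts/seeds, the three vegetable groups, the three fruit
#' groups). Range 0-9.
#'
#' @inheritParams fgds
#' @return Integer vector in 0..9.
#' @export
ncd_protect <- function(diet) {
  .score_items(.diet_matrix(diet), indicator_membership("NCD_PROTECT"))
}

#' NCD-Risk score
#'
#' Weighted count over eight items marking dietary risk factors for
#' non-communicable diseases: soft/energy/sports drinks, baked/grain-based
#' sweets, other sweets, processed meat (2 points), unprocessed red meat
#' (ruminant or non-ruminant, jointly 1 point), deep-fried foods, fast
#' food/instant noodles (jointly 1 point), salty snacks. Range 0-9.
#'
#' @inheritParams fgds
#' @return Integer vector in 0..9.
#' @export
ncd_risk <- function(diet) {
  .score_items(.diet_matrix(diet), indicator_membership("NCD_RISK"))
}

#' Global Dietary Recommendations (GDR) score
#'
#' `NCD-Protect - NCD-Risk + 9`, range 0-18. Higher scores indicate diets
#' more aligned with global dietary recommendations.
#'
#' @inheritParams fgds
#' @return Integer vector in 0..18.
#' @export
gdr <- function(diet) {
  m <- .diet_matrix(diet)
  .score_items(m, indicator_membership("NCD_PROTECT")) -
    .score_items(m, indicator_membership("NCD_RISK")) + 9L
}

#' Zero fruit or vegetable consumption
#'
#' `TRUE` when none of the six fruit/vegetable food groups was consumed.
#' Fruit juice and fruit-flavoured drinks count as a sweet beverage, not
#' as fruit.
#'
#' @inheritParams fgds
#' @return Logical vector.
#' @export
zero_fruit_veg <- function(diet) {
  !.any_group(.diet_matrix(diet), "FRUIT_VEG")
}

#' Sweet beverage consumption
#'
#' `TRUE` when any of soft/energy/sports drinks, fruit juice or
#' fruit-flavoured drinks, or sweetened tea/coffee/cocoa was consumed.
#'
#' @inheritParams fgds
#' @return Logical vector.
#' @export
sweet_beverage <- function(diet) {
  .any_group(.diet_matrix(diet), "SWEET_BEV")
}

#' Unhealthy/ultra-processed food consumption
#'
#' `TRUE` when any of the six unhealthy ultra-processed food groups
#' (baked/grain-based sweets, other sweets, salty snacks, instant noodles,
#' deep-fried foods, fast food) was consumed.
#'
#' @inheritParams fgds
#' @return Logical vector.
#' @export
unhealthy_upf <- function(diet) {
  .any_group(.diet_matrix(diet), "UPF")
}

#' Score a respondent table
#'
#' Computes the full indicator set for every respondent: FGDS, MDD-W
#' (restricted to women of reproductive age, `NA` otherwise), All-5 with
#' its five sub-components, NCD-Protect, NCD-Risk, GDR, and the three
#' binary consumption indicators.
#'
#' @param data A respondent table with the 29 food-group columns and, for
#'   MDD-W, `age_years` and `gender`; typically the output of
#'   [validate_diet()] or [generate_population()].
#' @param mddw_age_window Inclusive MDD-W eligibility window, default
#'   `c(15, 49)`.
#' @param fgds_processed_meat Passed to [indicator_membership()].
#' @return A tibble with one row per respondent: `respondent_id` (when
#'   present in `data`), `fgds`, `mddw`, `all5` + components,
#'   `ncd_protect`, `ncd_risk`, `gdr`, `zero_fruit_veg`, `sweet_beverage`,
#'   `unhealthy_upf`.
#' @examples
#' pop <- generate_population(default_scenario(seed = 1))
#' scores <- score_respondents(pop)
#' table(scores$fgds)
#' @export
score_respondents <- function(data, mddw_age_window = c(15L, 49L),
                              fgds_processed_meat = TRUE) {
  stopifnot(is.data.frame(data))
  out <- all5(data)
  out <- tibble::add_column(out,
    fgds = fgds(data, fgds_processed_meat),
    mddw = if (all(c("age_years", "gender") %in% names(data))) {
      mddw(data, data$age_years, data$gender, mddw_age_window,
           fgds_processed_meat)
    } else {
      rep(NA, nrow(data))
    },
    .before = 1L)
  out$ncd_protect <- ncd_protect(data)
  out$ncd_risk <- ncd_risk(data)
  out$gdr <- out$ncd_protect - out$ncd_risk + 9L
  out$zero_fruit_veg <- zero_fruit_veg(data)
  out$sweet_beverage <- sweet_beverage(data)
  out$unhealthy_upf <- unhealthy_upf(data)
  if ("respondent_id" %in% names(data)) {
    out <- tibble::add_column(out, respondent_id = data$respondent_id,
                              .before = 1L)
  }
  out
}

#' Write a score table to CSV
#'
#' One row per respondent; logical flags encoded 0/1 and the
#' not-applicable MDD-W encoded as an empty field.
#'
#' @param scores Output of [score_respondents()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(scores, path) {
  out <- scores
  for (col in names(out)) {
    if (is.logical(out[[col]])) out[[col]] <- as.integer(out[[col]])
  }
  readr::write_csv(out, path, na = "")
  invisible(path)
}
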