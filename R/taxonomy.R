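# Canonical DQQ food-group taxonomy and indicator membership maps.
#
# The 29 food groups are loaded from inst/extdata/dqq_food_groups.tsv, the
# single source of truth for codes, display labels, the promote/limit
# partition and row order. Column names in respondent tables are the codes
# themselves (lower_snake_case slugs of the display labels); consumption is
# coded 1 = consumed in the previous 24 h.

.dqq_cache <- new.env(parent = emptyenv())

#' Canonical DQQ food groups
#'
#' Returns the 29 food groups of the Diet Quality Questionnaire (DQQ), a
#' yes/no 24-hour dietary recall instrument, in their canonical report
#' order: 17 "foods to promote" followed by 12 "foods to limit".
#'
#' @return A tibble with one row per food group and columns `code`
#'   (stable identifier, also the respondent-table column name), `label`
#'   (display name), `category` (`"promote"` or `"limit"`) and
#'   `display_order` (1-29 report row order).
#' @examples
#' dqq_food_groups()
#' @export
dqq_food_groups <- function() {
  if (is.null(.dqq_cache$groups)) {
    path <- system.file("extdata", "dqq_food_groups.tsv", package = "dqqkit",
                        mustWork = TRUE)
    tab <- readr::read_tsv(path, col_types = readr::cols(
      code = readr::col_character(),
      label = readr::col_character(),
      category = readr::col_character(),
      display_order = readr::col_integer()
    ))
    stopifnot(nrow(tab) == 29L, !anyDuplicated(tab$code),
              all(tab$category %in% c("promote", "limit")))
    .dqq_cache$groups <- dplyr::arrange(tab, .data$display_order)
  }
  .dqq_cache$groups
}

#' Canonical food-group codes
#'
#' @return Character vector of the 29 food-group codes in canonical order.
#' @export
food_group_codes <- function() dqq_food_groups()$code

#' Diet quality indicator identifiers
#'
#' @return Character vector of the identifiers accepted by
#'   [indicator_membership()].
#' @export
indicator_ids <- function() {
  c("FGDS", "ALL5", "NCD_PROTECT", "NCD_RISK",
    "SWEET_BEV", "UPF", "FRUIT_VEG", "FOODS_TO_LIMIT")
}

# Frozen indicator -> item -> food-group mapping. Each item is a set of
# food-group codes scored "any consumed", carrying an integer point weight.
# Item sets within one indicator are pairwise disjoint.
.membership_list <- function(fgds_processed_meat = TRUE) {
  meat <- c("unprocessed_red_meat_ruminants", "unprocessed_red_meat_non_ruminants",
            "poultry", "fish_and_seafood")
  if (fgds_processed_meat) meat <- append(meat, "processed_meats", after = 2L)
  fv6 <- c("vitamin_a_rich_orange_vegetables", "dark_green_leafy_vegetables",
           "other_vegetables", "vitamin_a_rich_fruits", "citrus_fruits",
           "other_fruits")
  upf6 <- c("baked_grain_based_sweets", "other_sweets", "salty_snacks",
            "instant_noodles", "deep_fried_foods", "fast_foods")
  singletons <- function(codes) {
    stats::setNames(as.list(codes), codes)
  }
  list(
    # Ten aggregated food groups of the women's dietary diversity score
    # (MDD-W food-group structure); each item scores 1 point.
    FGDS = list(
      grains_tubers = c("grain_based_staple_foods", "whole_grains",
                        "roots_and_tubers"),
      pulses_legumes = "pulses_legumes",
      nuts_seeds = "nuts_and_seeds",
      dairy = c("cheese", "yogurt", "milk"),
      meat_poultry_fish = meat,
      eggs = "eggs",
      dark_green_leafy_vegetables = "dark_green_leafy_vegetables",
      other_vitamin_a_rich_fruits_vegetables =
        c("vitamin_a_rich_orange_vegetables", "vitamin_a_rich_fruits"),
      other_vegetables = "other_vegetables",
      other_fruits = c("citrus_fruits", "other_fruits")
    ),
    # Five food groups commonly recommended daily in food-based dietary
    # guidelines.
    ALL5 = list(
      starchy_staple = c("grain_based_staple_foods", "whole_grains",
                         "roots_and_tubers"),
      vegetable = c("vitamin_a_rich_orange_vegetables",
                    "dark_green_leafy_vegetables", "other_vegetables"),
      fruit = c("vitamin_a_rich_fruits", "citrus_fruits", "other_fruits"),
      pulse_nut_seed = c("pulses_legumes", "nuts_and_seeds"),
      animal_source = c("unprocessed_red_meat_ruminants",
                        "unprocessed_red_meat_non_ruminants",
                        "processed_meats", "poultry", "fish_and_seafood",
                        "eggs", "cheese", "yogurt", "milk")
    ),
    NCD_PROTECT = singletons(c(
      "whole_grains", "pulses_legumes", "nuts_and_seeds",
      "vitamin_a_rich_orange_vegetables", "dark_green_leafy_vegetables",
      "other_vegetables", "vitamin_a_rich_fruits", "citrus_fruits",
      "other_fruits"
    )),
    # Eight items, total weight 9: processed meat carries 2 points; fast
    # food and instant noodles form one item; the two unprocessed red meat
    # groups form one item.
    NCD_RISK = list(
      soft_drinks = "soft_drinks_and_energy_sports_drinks",
      baked_grain_based_sweets = "baked_grain_based_sweets",
      other_sweets = "other_sweets",
      processed_meats = "processed_meats",
      unprocessed_red_meat = c("unprocessed_red_meat_ruminants",
                               "unprocessed_red_meat_non_ruminants"),
      deep_fried_foods = "deep_fried_foods",
      fast_food_instant_noodles = c("fast_foods", "instant_noodles"),
      salty_snacks = "salty_snacks"
    ),
    SWEET_BEV = singletons(c(
      "soft_drinks_and_energy_sports_drinks",
      "fruit_juice_fruit_flavoured_drinks", "sweet_tea_coffee_cocoa"
    )),
    UPF = singletons(upf6),
    FRUIT_VEG = singletons(fv6),
    FOODS_TO_LIMIT = singletons(c(
      "processed_meats", "baked_grain_based_sweets", "other_sweets",
      "salty_snacks", "instant_noodles", "deep_fried_foods", "fast_foods",
      "sweet_tea_coffee_cocoa", "fruit_juice_fruit_flavoured_drinks",
      "soft_drinks_and_energy_sports_drinks"
    ))
  )
}

.item_weights <- function(indicator_id, items) {
  w <- rep(1L, length(items))
  if (indicator_id == "NCD_RISK") w[names(items) == "processed_meats"] <- 2L
  w
}

#' Indicator membership map
#'
#' The frozen mapping from a diet quality indicator to its scoring items.
#' Each item is a set of food-group codes scored "any consumed" and carries
#' an integer point weight. FGDS has 10 items of weight 1; NCD-Protect 9
#' items of weight 1; NCD-Risk 8 items totalling 9 points (processed meat
#' counts 2); All-5 five items; the binary consumption indicators
#' (SWEET_BEV, UPF, FRUIT_VEG, FOODS_TO_LIMIT) list their constituent
#' groups as weight-1 singletons and are scored "any group consumed".
#'
#' @param indicator_id One of [indicator_ids()].
#' @param fgds_processed_meat Should processed meats count toward the FGDS
#'   meat/poultry/fish item? Default `TRUE`, the DQQ convention; the
#'   published MDD-W item list does not enumerate the constituent groups,
#'   so this is exposed as a switch.
#' @return A list with elements `indicator_id` and `items`, a tibble with
#'   columns `item` (name), `groups` (list-column of food-group codes) and
#'   `weight` (integer points).
#' @examples
#' indicator_membership("NCD_RISK")
#' @export
indicator_membership <- function(indicator_id, fgds_processed_meat = TRUE) {
  ids <- indicator_ids()
  if (!is.character(indicator_id) || length(indicator_id) != 1L ||
      !indicator_id %in% ids) {
    stop("Unknown indicator_id ", deparse(indicator_id),
         "; valid ids: ", paste(ids, collapse = ", "), call. = FALSE)
  }
  items <- .membership_list(fgds_processed_meat)[[indicator_id]]
  list(
    indicator_id = indicator_id,
    items = tibble::tibble(
      item = names(items),
      groups = unname(items),
      weight = .item_weights(indicator_id, items)
    )
  )
}

# ---- validation ------------------------------------------------------------

.design_cols <- c("respondent_id", "country", "cluster_id", "weight",
                  "age_years", "gender", "education", "residence",
                  "wealth_quintile", "age_group")

.coerce_consumed <- function(x) {
  if (is.logical(x)) return(x)
  if (is.numeric(x)) {
    out <- rep(NA, length(x))
    out[x == 0] <- FALSE
    out[x == 1] <- TRUE
    out[is.na(x)] <- NA
    return(as.logical(out))
  }
  x_chr <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(x_chr))
  out[x_chr %in% c("1", "true", "yes", "t", "y")] <- TRUE
  out[x_chr %in% c("0", "false", "no", "f", "n")] <- FALSE
  as.logical(out)
}

#' Validate respondent diet columns
#'
#' Coerces the 29 food-group columns of a respondent table to logical
#' consumption flags. Accepted encodings are 0/1, logical, `"true"/"false"`
#' and `"yes"/"no"` (case-insensitive). Under the `"lenient"` policy a
#' missing food-group column, or a missing/uninterpretable value, is filled
#' as not-consumed with one warning per affected column; under `"strict"`
#' either is an error. Columns that are neither food groups nor the known
#' demographic/design fields are an error, so misspelt food-group columns
#' cannot pass silently.
#'
#' @param data A data frame with food-group columns named by
#'   [food_group_codes()], plus optional demographic/design columns
#'   (`respondent_id`, `country`, `cluster_id`, `weight`, `age_years`,
#'   `gender`, `education`, `residence`, `wealth_quintile`, `age_group`).
#' @param policy `"lenient"` (fill-and-warn) or `"strict"` (reject).
#' @return The input tibble with all 29 food-group columns present, logical
#'   and in canonical order after any passthrough columns. Validation
#'   messages are attached as the `"validation_warnings"` attribute (also
#'   signalled as R warnings under the lenient policy).
#' @export
validate_diet <- function(data, policy = c("lenient", "strict")) {
  policy <- match.arg(policy)
  stopifnot(is.data.frame(data))
  codes <- food_group_codes()
  known <- c(.design_cols, codes)
  unknown <- setdiff(names(data), known)
  if (length(unknown) > 0) {
    stop("Unrecognized column(s): ", paste(unknown, collapse = ", "),
         ". Food-group columns must use the canonical codes; see ",
         "food_group_codes().", call. = FALSE)
  }
  present <- intersect(codes, names(data))
  if (length(present) == 0L) {
    stop("No recognized food-group columns present.", call. = FALSE)
  }
  missing_cols <- setdiff(codes, present)
  warnings <- character(0)
  bad_cols <- character(0)

  out <- tibble::as_tibble(data)
  for (code in present) {
    v <- .coerce_consumed(out[[code]])
    n_bad <- sum(is.na(v))
    if (n_bad > 0) {
      if (policy == "strict") {
        bad_cols <- c(bad_cols, code)
      } else {
        v[is.na(v)] <- FALSE
        warnings <- c(warnings, sprintf(
          "column '%s': %d missing/uninterpretable value(s) filled as not-consumed",
          code, n_bad))
      }
    }
    out[[code]] <- v
  }
  if (policy == "strict" && (length(missing_cols) > 0 || length(bad_cols) > 0)) {
    stop("Strict validation failed. ",
         if (length(missing_cols) > 0)
           paste0("Missing food-group column(s): ",
                  paste(missing_cols, collapse = ", "), ". "),
         if (length(bad_cols) > 0)
           paste0("Uninterpretable values in: ",
                  paste(bad_cols, collapse = ", "), "."),
         call. = FALSE)
  }
  for (code in missing_cols) {
    out[[code]] <- rep(FALSE, nrow(out))
    warnings <- c(warnings, sprintf(
      "column '%s' absent: filled as not-consumed", code))
  }
  out <- out[c(intersect(.design_cols, names(out)), codes)]
  attr(out, "validation_warnings") <- warnings
  for (w in warnings) warning(w, call. = FALSE)
  out
}

#' Write diet columns back to a 0/1 record
#'
#' Inverse of [validate_diet()]: encodes the logical food-group columns as
#' integer 0/1 (the canonical CSV coding, 1 = consumed). Round-tripping
#' through `diet_to_record()` and `validate_diet()` is lossless.
#'
#' @param data A validated respondent tibble.
#' @return The tibble with food-group columns as integer 0/1.
#' @export
diet_to_record <- function(data) {
  codes <- intersect(food_group_codes(), names(data))
  for (code in codes) data[[code]] <- as.integer(data[[code]])
  data
}

# Internal: extract the n x 29 logical consumption matrix in canonical
# column order. Accepts a data frame (one row per respondent) or a named
# logical/0-1 vector (one respondent).
.diet_matrix <- function(diet) {
  codes <- food_group_codes()
  if (is.data.frame(diet)) {
    missing_cols <- setdiff(codes, names(diet))
    if (length(missing_cols) > 0) {
      stop("Missing food-group column(s): ",
           paste(missing_cols, collapse = ", "),
           ". Run validate_diet() first.", call. = FALSE)
    }
    m <- sapply(codes, function(code) as.logical(diet[[code]]))
    if (nrow(diet) == 1L) m <- matrix(m, nrow = 1L, dimnames = list(NULL, codes))
  } else {
    if (is.null(names(diet)) || !all(codes %in% names(diet))) {
      stop("A diet vector must be named by the 29 food-group codes.",
           call. = FALSE)
    }
    m <- matrix(as.logical(diet[codes]), nrow = 1L,
                dimnames = list(NULL, codes))
  }
  if (anyNA(m)) stop("Diet contains missing values; run validate_diet().",
                     call. = FALSE)
  m
}
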