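# End-to-end pipeline: read/validate respondents, assign age groups,
# score, summarise, test, and build the three report tables
# (sociodemographics, 29-food-group consumption, diet quality indicators)
# with gender and residence disaggregation.

#' Assign the analysis age group
#'
#' @param age_years Integer ages in completed years; all must be >= 15
#'   (the survey frame covers ages 15 and older).
#' @return Character vector: `"adolescent"` (15-19) or `"adult"` (20+).
#' @examples
#' assign_age_group(c(15, 19, 20, 64))
#' @export
assign_age_group <- function(age_years) {
  if (anyNA(age_years)) stop("Missing ages.", call. = FALSE)
  if (any(age_years < 15)) {
    stop("Age(s) below 15 are outside the survey frame: ",
         paste(utils::head(age_years[age_years < 15]), collapse = ", "),
         call. = FALSE)
  }
  ifelse(age_years <= 19, "adolescent", "adult")
}

#' Read a respondent CSV
#'
#' Reads a respondent table and validates its food-group columns (see
#' [validate_diet()]).
#'
#' @param path CSV path.
#' @param policy Validation policy, `"lenient"` or `"strict"`.
#' @return A validated respondent tibble.
#' @export
read_respondents <- function(path, policy = c("lenient", "strict")) {
  data <- readr::read_csv(path, show_col_types = FALSE,
                          progress = FALSE)
  validate_diet(data, policy = match.arg(policy))
}

# ---- cell and comparison formatting ---------------------------------------

.pct_cell <- function(pct, freq) sprintf("%.1f (%d)", pct, freq)
.median_cell <- function(m, q1, q3) {
  sprintf("%g [%g-%g]", m, q1, q3)
}

.not_testable <- function(test) {
  list(test = test, statistic = NA_real_, df1 = NA_real_, df2 = NA_real_,
       p_value = NA_real_, correction = NA_character_, display = "-")
}

.chi2_comparison <- function(outcome, group, cluster, weights) {
  if (length(unique(outcome)) < 2L || length(unique(group)) < 2L) {
    return(.not_testable("cluster_adjusted_chi2"))
  }
  cr <- cluster_adjusted_chi2(outcome, group, cluster, weights)
  list(test = cr$test, statistic = cr$statistic,
       df1 = unname(cr$df[1]), df2 = unname(cr$df[2]),
       p_value = cr$p_value, correction = cr$correction,
       display = sprintf("chi2 (%d, N = %d) = %.2g, %s",
                         as.integer(round(cr$df[1])), cr$n,
                         signif(cr$statistic, 3), format_p(cr$p_value)))
}

.mw_comparison <- function(values, group) {
  lev <- unique(group)
  if (length(lev) != 2L || length(unique(values)) < 2L) {
    return(.not_testable("mann_whitney"))
  }
  cr <- mann_whitney_u(values[group == lev[1]], values[group == lev[2]])
  list(test = cr$test, statistic = cr$statistic, df1 = NA_real_,
       df2 = NA_real_, p_value = cr$p_value, correction = cr$correction,
       display = format_p(cr$p_value))
}

.with_age_group <- function(data) {
  if (!"age_group" %in% names(data)) {
    data$age_group <- assign_age_group(data$age_years)
  }
  data
}

.group_levels <- function(data, group_var) {
  f <- data[[group_var]]
  if (is.null(f)) stop("Grouping variable '", group_var, "' not found.",
                       call. = FALSE)
  lev <- if (group_var == "age_group") {
    intersect(c("adolescent", "adult"), unique(f))
  } else {
    sort(unique(f))
  }
  if (length(lev) < 2L) {
    stop("Grouping variable '", group_var,
         "' needs >= 2 non-empty levels.", call. = FALSE)
  }
  lev
}

# ---- report builders -------------------------------------------------------

#' Food group consumption table
#'
#' One row per DQQ food group in canonical order, with the weighted
#' consumption percentage and unweighted frequency per group level and a
#' cluster-adjusted chi-square comparison across levels. Rows whose
#' outcome has no variation carry the not-testable marker `"-"`.
#'
#' @param data Validated respondent table; `age_group` is derived from
#'   `age_years` when absent.
#' @param group_var Grouping column, default `"age_group"`.
#' @return A tibble: `code`, `label`, `category`, then per level
#'   `pct_<level>`, `freq_<level>`, `n_<level>`, `cell_<level>`
#'   (`"44.3 (212)"` style), then `test`, `statistic`, `df1`, `df2`,
#'   `p_value`, `correction`, `comparison`.
#' @export
build_food_group_table <- function(data, group_var = "age_group") {
  data <- .with_age_group(data)
  lev <- .group_levels(data, group_var)
  groups <- dqq_food_groups()
  weights <- if ("weight" %in% names(data)) data$weight else rep(1, nrow(data))
  rows <- lapply(seq_len(nrow(groups)), function(i) {
    code <- groups$code[i]
    flags <- data[[code]]
    row <- tibble::tibble(code = code, label = groups$label[i],
                          category = groups$category[i])
    for (g in lev) {
      sel <- data[[group_var]] == g
      ps <- proportion_summary(flags[sel], weights[sel])
      row[[paste0("pct_", g)]] <- ps$proportion_pct
      row[[paste0("freq_", g)]] <- ps$frequency
      row[[paste0("n_", g)]] <- ps$n
      row[[paste0("cell_", g)]] <- .pct_cell(ps$proportion_pct, ps$frequency)
    }
    cmp <- .chi2_comparison(flags, data[[group_var]], data$cluster_id,
                            weights)
    row$test <- cmp$test; row$statistic <- cmp$statistic
    row$df1 <- cmp$df1; row$df2 <- cmp$df2
    row$p_value <- cmp$p_value; row$correction <- cmp$correction
    row$comparison <- cmp$display
    row
  })
  dplyr::bind_rows(rows)
}

#' Diet quality indicator table
#'
#' The indicator report: FGDS, NCD-Protect, NCD-Risk and GDR as medians
#' with interquartile ranges compared by Mann-Whitney U; MDD-W (among
#' women of reproductive age only), All-5 with its five sub-components,
#' zero fruit/vegetable, sweet beverage and unhealthy/ultra-processed
#' food as proportions compared by cluster-adjusted chi-square. Rows with
#' no outcome variation (e.g. a zero-prevalence flag) carry the
#' not-testable marker `"-"`.
#'
#' @param data Validated respondent table; `age_group` derived from
#'   `age_years` when absent.
#' @param scores Output of [score_respondents()] for `data`; computed on
#'   the fly when `NULL`.
#' @param group_var Grouping column: `"age_group"`, `"gender"` or
#'   `"residence"`.
#' @return A tibble, one row per indicator: `indicator`, `summary_type`
#'   (`"median_iqr"` or `"proportion"`), per level `n_<level>` plus either
#'   `median_/q1_/q3_<level>` or `pct_/freq_<level>`, `cell_<level>`
#'   (`"6 [5-8]"` / `"37.4 (179)"` style), then the comparison columns as
#'   in [build_food_group_table()].
#' @export
build_indicator_table <- function(data, scores = NULL,
                                  group_var = "age_group") {
  data <- .with_age_group(data)
  if (is.null(scores)) scores <- score_respondents(data)
  stopifnot(nrow(scores) == nrow(data))
  lev <- .group_levels(data, group_var)
  grp <- data[[group_var]]
  weights <- if ("weight" %in% names(data)) data$weight else rep(1, nrow(data))
  cluster <- data$cluster_id

  median_row <- function(id, values) {
    row <- tibble::tibble(indicator = id, summary_type = "median_iqr")
    for (g in lev) {
      mi <- median_iqr(values[grp == g])
      row[[paste0("n_", g)]] <- mi$n
      row[[paste0("median_", g)]] <- mi$median
      row[[paste0("q1_", g)]] <- mi$q1
      row[[paste0("q3_", g)]] <- mi$q3
      row[[paste0("cell_", g)]] <- .median_cell(mi$median, mi$q1, mi$q3)
    }
    cmp <- .mw_comparison(values, grp)
    row$test <- cmp$test; row$statistic <- cmp$statistic
    row$df1 <- cmp$df1; row$df2 <- cmp$df2
    row$p_value <- cmp$p_value; row$correction <- cmp$correction
    row$comparison <- cmp$display
    row
  }
  prop_row <- function(id, flags, subset = NULL) {
    keep <- if (is.null(subset)) rep(TRUE, length(flags)) else subset
    row <- tibble::tibble(indicator = id, summary_type = "proportion")
    nonempty <- character(0)
    for (g in lev) {
      sel <- keep & grp == g
      if (!any(sel)) {
        # restricted denominators (e.g. MDD-W) can empty a level
        row[[paste0("n_", g)]] <- 0L
        row[[paste0("pct_", g)]] <- NA_real_
        row[[paste0("freq_", g)]] <- 0L
        row[[paste0("cell_", g)]] <- "-"
        next
      }
      nonempty <- c(nonempty, g)
      ps <- proportion_summary(flags[sel], weights[sel])
      row[[paste0("n_", g)]] <- ps$n
      row[[paste0("pct_", g)]] <- ps$proportion_pct
      row[[paste0("freq_", g)]] <- ps$frequency
      row[[paste0("cell_", g)]] <- .pct_cell(ps$proportion_pct, ps$frequency)
    }
    keep <- keep & grp %in% nonempty
    cmp <- if (length(nonempty) < 2L) {
      .not_testable("cluster_adjusted_chi2")
    } else {
      .chi2_comparison(flags[keep], grp[keep], cluster[keep],
                       weights[keep])
    }
    row$test <- cmp$test; row$statistic <- cmp$statistic
    row$df1 <- cmp$df1; row$df2 <- cmp$df2
    row$p_value <- cmp$p_value; row$correction <- cmp$correction
    row$comparison <- cmp$display
    row
  }

  dplyr::bind_rows(
    median_row("fgds", scores$fgds),
    prop_row("mddw", scores$mddw, subset = !is.na(scores$mddw)),
    prop_row("all5", scores$all5),
    prop_row("all5_vegetable", scores$all5_vegetable),
    prop_row("all5_fruit", scores$all5_fruit),
    prop_row("all5_pulse_nut_seed", scores$all5_pulse_nut_seed),
    prop_row("all5_animal_source", scores$all5_animal_source),
    prop_row("all5_starchy_staple", scores$all5_starchy_staple),
    median_row("ncd_protect", scores$ncd_protect),
    median_row("ncd_risk", scores$ncd_risk),
    median_row("gdr", scores$gdr),
    prop_row("zero_fruit_veg", scores$zero_fruit_veg),
    prop_row("sweet_beverage", scores$sweet_beverage),
    prop_row("unhealthy_upf", scores$unhealthy_upf)
  )
}

#' Sociodemographic table
#'
#' Percent (frequency) per age group for gender, education, residence,
#' country and wealth quintile, with cluster-adjusted chi-square
#' comparisons. Multi-level blocks (country, wealth quintile) share one
#' test over the full cross-classification; `"unknown"` education is
#' excluded from its comparison and footnoted.
#'
#' @param data Validated respondent table; `age_group` derived from
#'   `age_years` when absent.
#' @return A tibble: `section`, `row_label`, per age group `pct_`,
#'   `freq_`, `n_`, `cell_` columns, the comparison columns, and
#'   `footnote` (e.g. counts excluded as unknown).
#' @export
build_sociodemographic_table <- function(data) {
  data <- .with_age_group(data)
  lev <- .group_levels(data, "age_group")
  weights <- if ("weight" %in% names(data)) data$weight else rep(1, nrow(data))
  grp <- data$age_group
  cluster <- data$cluster_id

  binary_block <- function(section, row_label, flags, keep = NULL) {
    keep <- if (is.null(keep)) rep(TRUE, length(flags)) else keep
    row <- tibble::tibble(section = section, row_label = row_label)
    for (g in lev) {
      sel <- keep & grp == g
      ps <- proportion_summary(flags[sel], weights[sel])
      row[[paste0("pct_", g)]] <- ps$proportion_pct
      row[[paste0("freq_", g)]] <- ps$frequency
      row[[paste0("n_", g)]] <- ps$n
      row[[paste0("cell_", g)]] <- .pct_cell(ps$proportion_pct, ps$frequency)
    }
    cmp <- .chi2_comparison(flags[keep], grp[keep], cluster[keep],
                            weights[keep])
    row$test <- cmp$test; row$statistic <- cmp$statistic
    row$df1 <- cmp$df1; row$df2 <- cmp$df2
    row$p_value <- cmp$p_value; row$correction <- cmp$correction
    row$comparison <- cmp$display
    n_excl <- sum(!keep)
    row$footnote <- if (n_excl > 0) {
      sprintf("%d respondent(s) with unknown response excluded", n_excl)
    } else {
      NA_character_
    }
    row
  }
  multi_block <- function(section, f) {
    f <- as.character(f)
    values <- sort(unique(f))
    cmp <- .chi2_comparison(f, grp, cluster, weights)
    rows <- lapply(seq_along(values), function(i) {
      v <- values[i]
      row <- tibble::tibble(section = section, row_label = v)
      for (g in lev) {
        sel <- grp == g
        ps <- proportion_summary(f[sel] == v, weights[sel])
        row[[paste0("pct_", g)]] <- ps$proportion_pct
        row[[paste0("freq_", g)]] <- ps$frequency
        row[[paste0("n_", g)]] <- ps$n
        row[[paste0("cell_", g)]] <- .pct_cell(ps$proportion_pct,
                                               ps$frequency)
      }
      # the block shares one test; attach it to the first row only
      if (i == 1L) {
        row$test <- cmp$test; row$statistic <- cmp$statistic
        row$df1 <- cmp$df1; row$df2 <- cmp$df2
        row$p_value <- cmp$p_value; row$correction <- cmp$correction
        row$comparison <- cmp$display
      } else {
        row$test <- NA_character_; row$statistic <- NA_real_
        row$df1 <- NA_real_; row$df2 <- NA_real_
        row$p_value <- NA_real_; row$correction <- NA_character_
        row$comparison <- NA_character_
      }
      row$footnote <- NA_character_
      row
    })
    dplyr::bind_rows(rows)
  }

  known_edu <- data$education != "unknown"
  dplyr::bind_rows(
    binary_block("gender", "female", data$gender == "female"),
    binary_block("education", "completed_primary_or_less",
                 data$education == "completed_primary_or_less",
                 keep = known_edu),
    binary_block("residence", "rural", data$residence == "rural"),
    multi_block("country", data$country),
    multi_block("wealth_quintile", data$wealth_quintile)
  )
}

#' Run the full analysis pipeline
#'
#' Simulate (or read), validate, score, and build every report table:
#' sociodemographics, food-group consumption and indicators by age group,
#' plus indicator and food-group tables disaggregated by gender and by
#' residence among adolescents.
#'
#' @param input A respondent data frame, a CSV path, or a `dqq_scenario`
#'   (in which case the population is generated first).
#' @param policy Validation policy for tabular input.
#' @param out_dir Optional directory; when given, all tables are written
#'   as CSV together with scores, the respondent data and a JSON run
#'   metadata sidecar.
#' @return A `dqq_report_bundle` list: `data`, `scores`,
#'   `sociodemographic_table`, `food_group_table`, `indicator_table`,
#'   `disaggregations` (gender/residence tables over adolescents),
#'   `run_metadata`.
#' @examples
#' \donttest{
#' bundle <- run_pipeline(default_scenario(seed = 1))
#' bundle$indicator_table$cell_adolescent
#' }
#' @export
run_pipeline <- function(input, policy = c("lenient", "strict"),
                         out_dir = NULL) {
  policy <- match.arg(policy)
  meta <- list(package_version = as.character(utils::packageVersion("dqqkit")),
               r_version = R.version.string,
               timestamp = format(Sys.time(), tz = "UTC"),
               policy = policy)
  if (inherits(input, "dqq_scenario")) {
    data <- generate_population(input)
    meta$input <- "scenario"
    meta$seed <- input$seed
    meta$config_hash <- attr(data, "provenance")$config_hash
  } else if (is.character(input) && length(input) == 1L) {
    data <- read_respondents(input, policy)
    meta$input <- input
  } else if (is.data.frame(input)) {
    data <- validate_diet(input, policy)
    meta$input <- "data.frame"
  } else {
    stop("input must be a data frame, a CSV path, or a dqq_scenario.",
         call. = FALSE)
  }
  meta$validation_warnings <- attr(data, "validation_warnings")
  data <- .with_age_group(data)
  scores <- score_respondents(data)
  adol <- data$age_group == "adolescent"

  disaggregate <- function(var) {
    sub <- data[adol, ]
    if (length(unique(sub[[var]])) < 2L) return(NULL)
    list(indicator_table = build_indicator_table(sub, scores[adol, ], var),
         food_group_table = build_food_group_table(sub, var))
  }
  bundle <- structure(list(
    data = data,
    scores = scores,
    sociodemographic_table = build_sociodemographic_table(data),
    food_group_table = build_food_group_table(data),
    indicator_table = build_indicator_table(data, scores),
    disaggregations = list(gender = disaggregate("gender"),
                           residence = disaggregate("residence")),
    run_metadata = meta
  ), class = "dqq_report_bundle")

  if (!is.null(out_dir)) write_report_bundle(bundle, out_dir)
  bundle
}

#' Write a report bundle to disk
#'
#' @param bundle A `dqq_report_bundle` from [run_pipeline()].
#' @param out_dir Directory (created if needed). Writes `respondents.csv`,
#'   `scores.csv`, one CSV per table, and `run_metadata.json`.
#' @return `out_dir`, invisibly.
#' @export
write_report_bundle <- function(bundle, out_dir) {
  stopifnot(inherits(bundle, "dqq_report_bundle"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(x, name) {
    readr::write_csv(x, file.path(out_dir, name), na = "")
  }
  w(diet_to_record(bundle$data), "respondents.csv")
  write_scores(bundle$scores, file.path(out_dir, "scores.csv"))
  w(bundle$sociodemographic_table, "sociodemographic_table.csv")
  w(bundle$food_group_table, "food_group_table.csv")
  w(bundle$indicator_table, "indicator_table_age.csv")
  for (var in names(bundle$disaggregations)) {
    dis <- bundle$disaggregations[[var]]
    if (is.null(dis)) next
    w(dis$indicator_table,
      sprintf("indicator_table_%s_adolescents.csv", var))
    w(dis$food_group_table,
      sprintf("food_group_table_%s_adolescents.csv", var))
  }
  jsonlite::write_json(bundle$run_metadata,
                       file.path(out_dir, "run_metadata.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(out_dir)
}
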