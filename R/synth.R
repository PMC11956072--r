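# Synthetic multistage-survey data generator.
#
# Emulates the structure of a pooled five-country 24-hour-recall survey:
# in-person countries are drawn as 100-125 primary sampling units with
# 8-10 interviews each, telephone countries as independent respondents
# (single-respondent clusters). Food-group consumption is generated with
# a beta random effect at cluster level so that within-cluster responses
# are exchangeable with marginal mean equal to the configured prevalence
# and pairwise intra-cluster correlation equal to the configured ICC.

#' Default simulation scenario
#'
#' Five countries totalling 5069 respondents: three in-person countries
#' (125 clusters x 8, 118 x 9, 125 x 8) and two telephone countries (1000
#' and 1007 respondents as single-respondent clusters). Adolescents (15-19
#' years) make up 9.5% of respondents. Food-group consumption prevalences
#' default, per age group, to the package's reference consumption table
#' (see `inst/extdata/default_prevalence.tsv`); demographic margins default
#' to the reference sociodemographic distribution.
#'
#' @param seed Integer seed stored in the config; [generate_population()]
#'   sets it before drawing.
#' @param icc Intra-cluster correlation of each food-group outcome within
#'   in-person clusters, default 0.05.
#' @param healthfulness_sd Standard deviation of an optional respondent-
#'   level latent "diet healthfulness" factor inducing cross-group
#'   correlation (positive tilt on foods to promote, negative on foods to
#'   limit, on the log-odds scale). Default 0: food groups independent
#'   given the cluster effect, which keeps derived indicator prevalences
#'   in closed form.
#' @return A `dqq_scenario` list: `countries` (tibble: `name`, `mode`,
#'   `n_clusters`, `interviews_per_cluster`, `n_respondents`),
#'   `adolescent_share`, `adult_age_range`, `demographics` (named margins
#'   per age group), `prevalence` (tibble: `code`, `adolescent`, `adult`,
#'   proportions in 0-1), `icc`, `healthfulness_sd`, `seed`.
#' @examples
#' cfg <- default_scenario(seed = 7)
#' sum(cfg$countries$n_respondents)
#' @export
default_scenario <- function(seed = 1L, icc = 0.05, healthfulness_sd = 0) {
  prev_path <- system.file("extdata", "default_prevalence.tsv",
                           package = "dqqkit", mustWork = TRUE)
  prev <- readr::read_tsv(prev_path, col_types = readr::cols(
    code = readr::col_character(), .default = readr::col_double()))
  cfg <- list(
    countries = tibble::tibble(
      name = c("Cambodia", "Indonesia", "Laos", "Philippines", "Vietnam"),
      mode = c("in_person", "in_person", "in_person",
               "telephone", "telephone"),
      n_clusters = c(125L, 118L, 125L, NA_integer_, NA_integer_),
      interviews_per_cluster = c(8L, 9L, 8L, NA_integer_, NA_integer_),
      n_respondents = c(1000L, 1062L, 1000L, 1000L, 1007L)
    ),
    adolescent_share = 0.095,
    adult_age_range = c(20L, 79L),
    demographics = list(
      gender_female = c(adolescent = 0.603, adult = 0.578),
      education_primary_or_less = c(adolescent = 0.345, adult = 0.408),
      residence_rural = c(adolescent = 0.639, adult = 0.552),
      wealth_quintile = rbind(
        adolescent = c(0.213, 0.173, 0.219, 0.205, 0.190),
        adult = c(0.180, 0.175, 0.186, 0.203, 0.256)
      )
    ),
    prevalence = tibble::tibble(
      code = prev$code,
      adolescent = prev$pct_adolescent / 100,
      adult = prev$pct_adult / 100
    ),
    icc = icc,
    healthfulness_sd = healthfulness_sd,
    seed = as.integer(seed)
  )
  class(cfg) <- "dqq_scenario"
  validate_scenario(cfg)
  cfg
}

#' Validate a simulation scenario
#'
#' @param config A `dqq_scenario` (see [default_scenario()]).
#' @return `config`, invisibly; errors on infeasible settings.
#' @export
validate_scenario <- function(config) {
  stopifnot(inherits(config, "dqq_scenario"))
  ctry <- config$countries
  stopifnot(nrow(ctry) >= 1, all(ctry$mode %in% c("in_person", "telephone")))
  ip <- ctry[ctry$mode == "in_person", ]
  if (nrow(ip) > 0) {
    if (any(is.na(ip$n_clusters)) || any(is.na(ip$interviews_per_cluster)) ||
        any(ip$n_clusters < 100L | ip$n_clusters > 125L) ||
        any(ip$interviews_per_cluster < 8L | ip$interviews_per_cluster > 10L)) {
      stop("In-person countries need 100-125 clusters with 8-10 interviews ",
           "per cluster.", call. = FALSE)
    }
    if (any(ip$n_respondents != ip$n_clusters * ip$interviews_per_cluster)) {
      stop("n_respondents must equal n_clusters * interviews_per_cluster ",
           "for in-person countries.", call. = FALSE)
    }
  }
  tel <- ctry[ctry$mode == "telephone", ]
  if (nrow(tel) > 0 && any(is.na(tel$n_respondents) | tel$n_respondents < 1))
    stop("Telephone countries need n_respondents >= 1.", call. = FALSE)
  if (config$adolescent_share < 0 || config$adolescent_share > 1)
    stop("adolescent_share must be in [0, 1].", call. = FALSE)
  if (config$icc < 0 || config$icc >= 1)
    stop("icc must be in [0, 1).", call. = FALSE)
  dm <- config$demographics
  probs <- c(dm$gender_female, dm$education_primary_or_less,
             dm$residence_rural, as.vector(dm$wealth_quintile))
  if (any(probs < 0 | probs > 1) ||
      any(abs(rowSums(dm$wealth_quintile) - 1) > 1e-8))
    stop("Demographic margins must be probabilities (wealth quintiles ",
         "summing to 1).", call. = FALSE)
  prev <- config$prevalence
  stopifnot(setequal(prev$code, food_group_codes()))
  if (any(prev$adolescent < 0 | prev$adolescent > 1 |
          prev$adult < 0 | prev$adult > 1))
    stop("Prevalences must be in [0, 1].", call. = FALSE)
  invisible(config)
}

#' Generate cluster-correlated binary consumption
#'
#' Draws one binary outcome per respondent with marginal mean `prevalence`
#' and pairwise within-cluster correlation approximately `icc`, via a
#' beta-distributed cluster-level prevalence: each cluster draws
#' `p_k ~ Beta(a, b)` with `a = p(1-icc)/icc`, `b = (1-p)(1-icc)/icc`
#' (so `E[p_k] = p` and `Cor = icc` exactly), then respondents draw
#' independent Bernoulli(`p_k`). `icc = 0` reduces to independent draws.
#' Uses the current RNG stream; seed with `set.seed()` for
#' reproducibility.
#'
#' @param prevalence Marginal consumption probability in \[0, 1\].
#' @param icc Intra-cluster correlation in \[0, 1).
#' @param cluster Cluster assignment per respondent.
#' @return Logical vector, one draw per respondent.
#' @export
generate_consumption <- function(prevalence, icc, cluster) {
  if (!is.numeric(prevalence) || length(prevalence) != 1L ||
      prevalence < 0 || prevalence > 1)
    stop("prevalence must be a single value in [0, 1].", call. = FALSE)
  if (!is.numeric(icc) || length(icc) != 1L || icc < 0 || icc >= 1)
    stop("icc must be a single value in [0, 1).", call. = FALSE)
  n <- length(cluster)
  if (icc == 0 || prevalence %in% c(0, 1)) {
    return(stats::runif(n) < prevalence)
  }
  ids <- unique(cluster)
  a <- prevalence * (1 - icc) / icc
  b <- (1 - prevalence) * (1 - icc) / icc
  p_k <- stats::setNames(stats::rbeta(length(ids), a, b), ids)
  stats::runif(n) < p_k[as.character(cluster)]
}

# Per-respondent cluster-conditional consumption probabilities for
# stratum-specific prevalences, with a cluster effect shared across
# strata: one uniform per cluster, mapped through each stratum's beta
# quantile function. Conditional on the cluster, respondents are
# independent Bernoulli draws, so marginal mean = prevalence and
# within-stratum within-cluster correlation = icc; strata in the same
# cluster are positively correlated, as in a real area sample.
.cluster_probs <- function(prev_by_stratum, stratum, icc, cluster) {
  p_i <- unname(prev_by_stratum[stratum])
  if (icc == 0) return(p_i)
  ids <- unique(cluster)
  u_k <- stats::setNames(stats::runif(length(ids)), ids)
  u_i <- u_k[as.character(cluster)]
  out <- p_i
  for (s in names(prev_by_stratum)) {
    sel <- stratum == s
    p <- prev_by_stratum[[s]]
    if (!any(sel) || p %in% c(0, 1)) next
    a <- p * (1 - icc) / icc
    b <- (1 - p) * (1 - icc) / icc
    out[sel] <- stats::qbeta(u_i[sel], a, b)
  }
  out
}

#' Generate a synthetic respondent table
#'
#' Draws a full multi-country respondent table under a scenario
#' configuration: cluster structure per country, ages (adolescent share,
#' then uniform 15-19 or a geometrically tapered adult distribution),
#' demographics from the configured per-age-group margins, and the 29
#' food-group consumption flags with the configured per-stratum
#' prevalences and intra-cluster correlation. Deterministic given the
#' config (which includes the seed): draws are ordered by country, then
#' demographic field, then food group in canonical order.
#'
#' @param config A `dqq_scenario`, e.g. [default_scenario()].
#' @return A tibble with one row per respondent: `respondent_id`,
#'   `country`, `cluster_id`, `weight` (1), `age_years`, `gender`,
#'   `education`, `residence`, `wealth_quintile` and the 29 food-group
#'   columns (logical). Provenance (seed and config hash) is attached as
#'   the `"provenance"` attribute.
#' @examples
#' pop <- generate_population(default_scenario(seed = 42))
#' nrow(pop)
#' @export
generate_population <- function(config) {
  validate_scenario(config)
  set.seed(config$seed)
  dm <- config$demographics
  prev <- config$prevalence
  ages_adult <- seq(config$adult_age_range[1], config$adult_age_range[2])
  # tapered adult age pyramid (documented in the methods vignette)
  w_adult <- exp(-(ages_adult - ages_adult[1]) / 25)

  pieces <- lapply(seq_len(nrow(config$countries)), function(i) {
    ctry <- config$countries[i, ]
    if (ctry$mode == "in_person") {
      cluster_id <- sprintf("%s_c%03d",
                            ctry$name,
                            rep(seq_len(ctry$n_clusters),
                                each = ctry$interviews_per_cluster))
    } else {
      cluster_id <- sprintf("%s_r%04d", ctry$name,
                            seq_len(ctry$n_respondents))
    }
    n <- ctry$n_respondents
    is_adol <- stats::runif(n) < config$adolescent_share
    age <- integer(n)
    age[is_adol] <- sample(15:19, sum(is_adol), replace = TRUE)
    age[!is_adol] <- sample(ages_adult, sum(!is_adol), replace = TRUE,
                            prob = w_adult)
    stratum <- ifelse(is_adol, "adolescent", "adult")
    gender <- ifelse(stats::runif(n) < dm$gender_female[stratum],
                     "female", "male")
    education <- ifelse(
      stats::runif(n) < dm$education_primary_or_less[stratum],
      "completed_primary_or_less", "more_than_primary")
    residence <- ifelse(stats::runif(n) < dm$residence_rural[stratum],
                        "rural", "urban")
    wq <- integer(n)
    for (s in c("adolescent", "adult")) {
      sel <- stratum == s
      if (any(sel)) {
        wq[sel] <- sample(1:5, sum(sel), replace = TRUE,
                          prob = dm$wealth_quintile[s, ])
      }
    }
    out <- tibble::tibble(
      respondent_id = sprintf("%s_%05d", ctry$name, seq_len(n)),
      country = ctry$name, cluster_id = cluster_id, weight = 1,
      age_years = age, gender = gender, education = education,
      residence = residence, wealth_quintile = wq
    )
    hf <- if (config$healthfulness_sd > 0) {
      stats::rnorm(n, 0, config$healthfulness_sd)
    } else {
      NULL
    }
    promote <- dqq_food_groups()$category == "promote"
    for (g in seq_len(nrow(prev))) {
      code <- prev$code[g]
      p_s <- c(adolescent = prev$adolescent[g], adult = prev$adult[g])
      p_i <- .cluster_probs(p_s, stratum, config$icc, cluster_id)
      if (!is.null(hf)) {
        # latent healthfulness tilts the cluster-conditional log-odds:
        # positive on foods to promote, negative on foods to limit
        sgn <- if (promote[g]) 1 else -1
        p_i <- stats::plogis(
          stats::qlogis(pmin(pmax(p_i, 1e-9), 1 - 1e-9)) + sgn * hf)
      }
      out[[code]] <- stats::runif(n) < p_i
    }
    out
  })
  out <- dplyr::bind_rows(pieces)
  attr(out, "provenance") <- list(seed = config$seed,
                                  config_hash = rlang::hash(config))
  out
}

#' Write a generated population and its scenario
#'
#' Writes the respondent CSV (0/1 consumption coding) and a YAML sidecar
#' with the full scenario, including the seed, for reproducibility.
#'
#' @param data Output of [generate_population()].
#' @param path CSV file path; the scenario is written next to it as
#'   `<path>.scenario.yaml`.
#' @param config The `dqq_scenario` used.
#' @return `path`, invisibly.
#' @export
write_population <- function(data, path, config = NULL) {
  readr::write_csv(diet_to_record(data), path, na = "")
  if (!is.null(config)) {
    yaml::write_yaml(.scenario_to_list(config),
                     paste0(path, ".scenario.yaml"))
  }
  invisible(path)
}

.scenario_to_list <- function(config) {
  out <- unclass(config)
  out$countries <- as.data.frame(out$countries)
  out$prevalence <- as.data.frame(out$prevalence)
  out$demographics$wealth_quintile <-
    as.data.frame(out$demographics$wealth_quintile)
  out
}
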