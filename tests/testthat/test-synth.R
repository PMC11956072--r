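test_that("default scenario encodes the reference study structure", {
  cfg <- default_scenario(seed = 3)
  expect_equal(nrow(cfg$countries), 5L)
  expect_equal(sum(cfg$countries$n_respondents), 5069L)
  expect_equal(cfg$adolescent_share, 0.095)
  prev <- cfg$prevalence
  expect_equal(prev$adolescent[prev$code == "other_sweets"], 0.420)
  expect_equal(prev$adult[prev$code == "processed_meats"], 0.222)
  expect_equal(prev$adolescent[prev$code == "instant_noodles"], 0.443)
  expect_equal(prev$adult[prev$code == "salty_snacks"], 0.140)
  ip <- cfg$countries[cfg$countries$mode == "in_person", ]
  expect_true(all(ip$n_clusters >= 100 & ip$n_clusters <= 125))
  expect_true(all(ip$interviews_per_cluster >= 8 &
                    ip$interviews_per_cluster <= 10))
})

test_that("scenario validation rejects infeasible settings", {
  cfg <- default_scenario()
  bad <- cfg; bad$countries$n_clusters[1] <- 90L
  expect_error(validate_scenario(bad), "100-125")
  bad <- cfg; bad$icc <- 1
  expect_error(validate_scenario(bad), "icc")
  bad <- cfg; bad$prevalence$adult[3] <- 1.2
  expect_error(validate_scenario(bad), "0, 1")
  bad <- cfg; bad$demographics$wealth_quintile["adult", ] <- rep(0.5, 5)
  expect_error(validate_scenario(bad), "summing to 1")
})

test_that("generate_consumption honours its marginal moments", {
  cl <- rep(1:120, each = 10)
  set.seed(61)
  expect_true(all(!generate_consumption(0, 0.3, cl)))
  expect_true(all(generate_consumption(1, 0.3, cl)))

  # icc = 0: empirical prevalence within 3 binomial SEs
  y <- generate_consumption(0.5, 0, seq_len(100000))
  expect_lt(abs(mean(y) - 0.5), 3 * sqrt(0.25 / 100000))

  # icc recovery from the ANOVA estimator
  y2 <- generate_consumption(0.3, 0.05, cl)
  expect_lt(abs(intra_cluster_correlation(y2, cl) - 0.05), 0.03)

  # marginal prevalence under clustering, within 3 design-adjusted SEs
  set.seed(62)
  cl3 <- rep(1:1000, each = 10)
  y3 <- generate_consumption(0.3, 0.05, cl3)
  deff <- 1 + 9 * 0.05
  expect_lt(abs(mean(y3) - 0.3), 3 * sqrt(0.3 * 0.7 * deff / 10000))

  expect_error(generate_consumption(1.2, 0, cl), "prevalence")
  expect_error(generate_consumption(0.5, 1, cl), "icc")
})

test_that("generate_population is deterministic and structurally sound", {
  cfg <- default_scenario(seed = 99)
  pop1 <- generate_population(cfg)
  pop2 <- generate_population(cfg)
  expect_identical(pop1, pop2)

  expect_equal(nrow(pop1), 5069L)
  expect_equal(anyDuplicated(pop1$respondent_id), 0L)
  expect_true(all(!is.na(pop1$cluster_id)))
  expect_true(all(pop1$age_years >= 15))
  # telephone countries are single-respondent clusters
  vn <- pop1[pop1$country == "Vietnam", ]
  expect_equal(anyDuplicated(vn$cluster_id), 0L)
  kh <- pop1[pop1$country == "Cambodia", ]
  expect_equal(length(unique(kh$cluster_id)), 125L)
  expect_true(all(table(kh$cluster_id) == 8L))
  # every respondent passes strict validation after a CSV-style round trip
  expect_silent(validate_diet(diet_to_record(pop1), "strict"))

  # age groups partition exactly at the 15-19 / 20+ boundary
  ag <- assign_age_group(pop1$age_years)
  expect_equal(ag == "adolescent", pop1$age_years <= 19)
})

test_that("zero adolescent share produces an all-adult sample", {
  cfg <- default_scenario(seed = 5)
  cfg$adolescent_share <- 0
  pop <- generate_population(cfg)
  expect_true(all(pop$age_years >= 20))
})

test_that("generated prevalences track the configured table", {
  cfg <- default_scenario(seed = 123)
  pop <- generate_population(cfg)
  stratum <- assign_age_group(pop$age_years)
  prev <- cfg$prevalence
  m_bar <- 9  # average interviews per in-person cluster, ~60% of sample
  for (code in c("instant_noodles", "other_sweets", "dark_green_leafy_vegetables")) {
    for (s in c("adolescent", "adult")) {
      p <- prev[[s]][prev$code == code]
      emp <- mean(pop[[code]][stratum == s])
      n_s <- sum(stratum == s)
      deff <- 1 + (m_bar - 1) * cfg$icc
      expect_lt(abs(emp - p), 3 * sqrt(p * (1 - p) * deff / n_s))
    }
  }
})

test_that("the latent healthfulness factor induces cross-group correlation", {
  cfg <- default_scenario(seed = 17, icc = 0, healthfulness_sd = 1.5)
  pop <- generate_population(cfg)
  # two foods to limit become positively associated...
  r_limit <- cor(pop$other_sweets, pop$salty_snacks)
  expect_gt(r_limit, 0.05)
  # ...and promote/limit pairs negatively
  r_cross <- cor(pop$dark_green_leafy_vegetables, pop$salty_snacks)
  expect_lt(r_cross, -0.05)
})

test_that("populations serialise with their scenario sidecar", {
  cfg <- default_scenario(seed = 2)
  cfg$countries <- cfg$countries[4, ]   # one small telephone country
  cfg$countries$n_respondents <- 50L
  pop <- generate_population(cfg)
  path <- withr::local_tempfile(fileext = ".csv")
  write_population(pop, path, cfg)
  expect_true(file.exists(paste0(path, ".scenario.yaml")))
  back <- read_respondents(path, "strict")
  expect_equal(as.data.frame(back[food_group_codes()]),
               as.data.frame(pop[food_group_codes()]), ignore_attr = TRUE)
  side <- yaml::read_yaml(paste0(path, ".scenario.yaml"))
  expect_equal(side$seed, 2L)
})
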