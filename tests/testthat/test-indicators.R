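# A diet with only the named groups consumed.
diet_of <- function(...) {
  codes <- food_group_codes()
  on <- c(...)
  stopifnot(all(on %in% codes))
  tibble::as_tibble(as.list(setNames(codes %in% on, codes)))
}

test_that("FGDS counts aggregated food groups", {
  expect_equal(fgds(diet_of()), 0L)
  expect_equal(fgds(enumerate_diets(food_group_codes()[1])[2, ]), 1L)
  all_on <- diet_of(food_group_codes())
  expect_equal(fgds(all_on), 10L)
  # hand count against the frozen item mapping: 6 distinct items hit
  d6 <- diet_of("grain_based_staple_foods", "dark_green_leafy_vegetables",
                "eggs", "fish_and_seafood", "other_fruits",
                "other_vegetables")
  expect_equal(fgds(d6), 6L)
  # constituents of one item count once
  expect_equal(fgds(diet_of("cheese", "yogurt", "milk")), 1L)
})

test_that("MDD-W applies only to women of reproductive age", {
  d5 <- diet_of("grain_based_staple_foods", "other_vegetables",
                "citrus_fruits", "pulses_legumes", "eggs")
  expect_equal(fgds(d5), 5L)
  expect_true(mddw(d5, 17L, "female"))
  expect_true(mddw(d5, 49L, "female"))
  expect_true(is.na(mddw(d5, 50L, "female")))
  expect_true(is.na(mddw(d5, 17L, "male")))
  d4 <- diet_of("grain_based_staple_foods", "other_vegetables",
                "citrus_fruits", "pulses_legumes")
  expect_false(mddw(d4, 17L, "female"))
  # the eligibility window is a parameter
  expect_false(is.na(mddw(d5, 55L, "female", age_window = c(15L, 60L))))
})

test_that("All-5 is the conjunction of its five components", {
  res <- all5(diet_of(food_group_codes()))
  expect_true(res$all5)
  expect_true(all(unlist(res[1, ])))
  # minimal witness: one group per component
  w <- all5(diet_of("grain_based_staple_foods", "other_vegetables",
                    "citrus_fruits", "pulses_legumes", "eggs"))
  expect_true(w$all5)
  nofruit <- all5(diet_of("grain_based_staple_foods", "other_vegetables",
                          "pulses_legumes", "eggs"))
  expect_false(nofruit$all5)
  expect_false(nofruit$all5_fruit)
  expect_true(nofruit$all5_vegetable)
})

test_that("NCD-Protect and NCD-Risk score their item weights", {
  expect_equal(ncd_protect(diet_of()), 0L)
  expect_equal(ncd_protect(diet_of(indicator_groups("NCD_PROTECT"))), 9L)
  expect_equal(ncd_protect(diet_of("whole_grains", "citrus_fruits")), 2L)

  expect_equal(ncd_risk(diet_of("processed_meats")), 2L)
  expect_equal(ncd_risk(diet_of(indicator_groups("NCD_RISK"))), 9L)
  expect_equal(ncd_risk(diet_of("fast_foods", "instant_noodles")), 1L)
  expect_equal(ncd_risk(diet_of("unprocessed_red_meat_ruminants",
                                "unprocessed_red_meat_non_ruminants")), 1L)
})

test_that("GDR score spans 0-18 and equals protect - risk + 9", {
  expect_equal(gdr(diet_of()), 9L)
  expect_equal(gdr(diet_of(indicator_groups("NCD_PROTECT"))), 18L)
  expect_equal(gdr(diet_of(indicator_groups("NCD_RISK"))), 0L)
})

test_that("consumption flags follow the frozen membership sets", {
  none <- diet_of()
  expect_true(zero_fruit_veg(none))
  expect_false(sweet_beverage(none))
  expect_false(unhealthy_upf(none))
  # fruit juice is a sweet beverage, not a fruit
  juice <- diet_of("fruit_juice_fruit_flavoured_drinks")
  expect_true(zero_fruit_veg(juice))
  expect_true(sweet_beverage(juice))
  expect_true(unhealthy_upf(diet_of("salty_snacks")))
})

test_that("exhaustive enumeration reproduces the score ranges", {
  pr <- ncd_protect(enumerate_diets(indicator_groups("NCD_PROTECT")))
  expect_equal(range(pr), c(0L, 9L))
  expect_equal(sort(unique(pr)), 0:9)

  rk <- ncd_risk(enumerate_diets(indicator_groups("NCD_RISK")))
  expect_equal(range(rk), c(0L, 9L))
  expect_equal(sort(unique(rk)), 0:9)

  sent <- enumerate_diets(fgds_sentinels())
  fs <- fgds(sent)
  expect_equal(range(fs), c(0L, 10L))
  # minimum FGDS among MDD-W-positive patterns is exactly 5
  flags <- mddw(sent, 17L, rep("female", nrow(sent)))
  expect_equal(min(fs[flags]), 5L)
})

test_that("scores are monotone in added consumption", {
  set.seed(101)
  codes <- food_group_codes()
  for (rep in 1:200) {
    d <- random_diets(1, p = runif(1, 0.1, 0.8))
    off <- codes[!unlist(d[1, codes])]
    if (length(off) == 0) next
    d2 <- d
    d2[[sample(off, 1)]] <- TRUE
    expect_gte(fgds(d2), fgds(d))
    expect_gte(ncd_protect(d2), ncd_protect(d))
    expect_gte(ncd_risk(d2), ncd_risk(d))
    a1 <- all5(d); a2 <- all5(d2)
    expect_false(a1$all5 && !a2$all5)
    expect_false(sweet_beverage(d) && !sweet_beverage(d2))
    expect_false(unhealthy_upf(d) && !unhealthy_upf(d2))
    expect_false(!zero_fruit_veg(d) && zero_fruit_veg(d2))
  }
})

test_that("score_respondents fills every indicator consistently", {
  set.seed(7)
  diet <- random_diets(300, p = 0.35)
  data <- as_respondents(diet,
                         age_years = sample(15:80, 300, TRUE),
                         gender = sample(c("female", "male"), 300, TRUE))
  sc <- score_respondents(data)
  expect_equal(nrow(sc), 300L)
  expect_equal(sc$respondent_id, data$respondent_id)
  expect_equal(sc$gdr, sc$ncd_protect - sc$ncd_risk + 9L)
  expect_equal(sc$all5,
               sc$all5_starchy_staple & sc$all5_vegetable & sc$all5_fruit &
                 sc$all5_pulse_nut_seed & sc$all5_animal_source)
  # zero fruit/vegetable caps FGDS at 6 (only 6 non-fruit/veg items)
  expect_true(all(sc$fgds[sc$zero_fruit_veg] <= 6L))
  eligible <- data$gender == "female" & data$age_years <= 49
  expect_equal(is.na(sc$mddw), !eligible)
  expect_equal(sc$mddw[eligible], sc$fgds[eligible] >= 5L)

  empty <- score_respondents(as_respondents(diet_of(), age_years = 17L))
  expect_equal(empty$fgds, 0L)
  expect_equal(empty$gdr, 9L)
  expect_true(empty$zero_fruit_veg)
  full <- score_respondents(as_respondents(diet_of(food_group_codes()),
                                           age_years = 40L,
                                           gender = "male"))
  expect_equal(full$fgds, 10L)
  expect_true(full$all5)
  expect_equal(full$ncd_risk, 9L)
  expect_true(is.na(full$mddw))
})
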