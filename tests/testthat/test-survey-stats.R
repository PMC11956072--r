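test_that("proportion_summary reports weighted percent, unweighted count", {
  flags <- c(rep(TRUE, 300), rep(FALSE, 179))
  ps <- proportion_summary(flags)
  expect_equal(ps$n, 479L)
  expect_equal(ps$frequency, 300L)
  expect_equal(sprintf("%.1f", ps$proportion_pct), "62.6")

  expect_equal(proportion_summary(rep(FALSE, 10))$proportion_pct, 0)

  # doubling the weight of the TRUE stratum moves the proportion but
  # not the frequency
  w <- ifelse(flags, 2, 1)
  psw <- proportion_summary(flags, w)
  expect_equal(psw$frequency, 300L)
  expect_equal(psw$proportion_pct, 100 * 600 / (600 + 179))
  expect_error(proportion_summary(logical(0)), "Empty")
})

test_that("median_iqr uses interpolated percentiles", {
  expect_equal(unlist(median_iqr(1:9)[, c("median", "q1", "q3")]),
               c(median = 5, q1 = 3, q3 = 7))
  expect_equal(unlist(median_iqr(7)[, c("median", "q1", "q3")]),
               c(median = 7, q1 = 7, q3 = 7))
  # type-7 interpolation on {0,0,9,9}
  expect_equal(unlist(median_iqr(c(0, 0, 9, 9))[, c("median", "q1", "q3")]),
               c(median = 4.5, q1 = 0, q3 = 9))
  expect_error(median_iqr(numeric(0)), "Empty")
})

test_that("Mann-Whitney: exact enumeration on small samples", {
  r <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(r$p_value, 1 / 3)
  expect_equal(r$statistic, 0)
  expect_equal(r$method, "exact_enumeration")

  same <- mann_whitney_u(c(1, 2, 3), c(3, 1, 2))
  expect_gte(same$p_value, 0.99)

  expect_warning(deg <- mann_whitney_u(rep(2, 5), rep(2, 3)), "identical")
  expect_equal(deg$p_value, 1)

  # parameterised equivalence with the independent enumeration oracle,
  # including heavy ties
  set.seed(11)
  for (i in 1:25) {
    nx <- sample(2:8, 1); ny <- sample(2:8, 1)
    x <- sample(1:4, nx, TRUE); y <- sample(1:4, ny, TRUE)
    if (length(unique(c(x, y))) == 1L) next
    got <- mann_whitney_u(x, y)
    want <- oracle_mw_exact(x, y)
    expect_equal(got$statistic, want$U)
    expect_equal(got$p_value, want$p_value, tolerance = 1e-12)
  }
})

test_that("Mann-Whitney: normal approximation is tie-corrected and agrees", {
  set.seed(21)
  x <- sample(1:5, 40, TRUE); y <- sample(1:5, 55, TRUE) + 0.5 * rbinom(55, 1, 0.5)
  got <- mann_whitney_u(x, y)
  expect_equal(got$method, "normal_approximation")
  ref <- suppressWarnings(stats::wilcox.test(x, y, correct = FALSE,
                                             exact = FALSE))
  expect_equal(got$statistic, unname(ref$statistic))
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-10)

  # invariance under strictly monotone transforms of the pooled values
  t1 <- mann_whitney_u(exp(x), exp(y))
  expect_equal(t1$statistic, got$statistic)
  expect_equal(t1$p_value, got$p_value)
})

test_that("cluster chi-square: no association gives ~zero statistic", {
  # exactly independent 2x2, one respondent per cluster
  y <- rep(c(TRUE, FALSE), each = 40)
  g <- rep(rep(c("a", "b"), each = 20), 2)
  cr <- cluster_adjusted_chi2(y, g, seq_along(y))
  expect_lt(cr$statistic, 1e-10)
  expect_gt(cr$p_value, 0.999)
})

test_that("cluster chi-square matches the direct-formula 2x2 oracle", {
  set.seed(31)
  for (i in 1:20) {
    K <- sample(6:10, 1)
    m <- sample(5:9, 1)
    cl <- rep(seq_len(K), each = m)
    n <- K * m
    y <- generate_consumption(runif(1, 0.3, 0.7), 0.1, cl)
    g <- sample(c("u", "v"), n, TRUE)
    if (length(unique(y)) < 2 || length(unique(g)) < 2) next
    w <- if (i %% 2 == 0) runif(n, 0.5, 2) else rep(1, n)
    got <- cluster_adjusted_chi2(y, g, cl, weights = w)
    want <- oracle_chi2_2x2(y, g, cl, w)
    expect_equal(got$statistic, want$statistic, tolerance = 1e-6)
    expect_equal(got$p_value, want$p_value, tolerance = 1e-6)
    expect_equal(got$correction, "rao_scott_second_order")
  }
})

test_that("with one respondent per cluster the correction is (n-1)/n", {
  set.seed(41)
  n <- 120
  y <- factor(sample(c("low", "mid", "high"), n, TRUE))
  g <- factor(sample(c("a", "b"), n, TRUE))
  cr <- cluster_adjusted_chi2(y, g, seq_len(n))
  classical <- suppressWarnings(stats::chisq.test(table(y, g),
                                                  correct = FALSE))
  expect_equal(cr$statistic,
               unname(classical$statistic) * (n - 1) / n,
               tolerance = 1e-8)
  expect_equal(unname(cr$df[1]), 2, tolerance = 1e-6)
})

test_that("cluster chi-square guards its degenerate inputs", {
  y <- c(TRUE, FALSE, TRUE, FALSE)
  expect_error(cluster_adjusted_chi2(y, c("a", "a", "b", "b"),
                                     rep("c1", 4)), "clusters")
  f <- factor(c("a", "a", "b", "b"), levels = c("a", "b", "ghost"))
  expect_warning(cluster_adjusted_chi2(y, f, 1:4), "ghost")
  expect_error(suppressWarnings(
    cluster_adjusted_chi2(rep(TRUE, 4), c("a", "a", "b", "b"), 1:4)),
    "levels")
})

test_that("ICC estimator hits its limiting cases and recovers icc", {
  # identical within clusters, differing across -> 1
  y <- rep(c(1, 0, 1, 0), each = 10)
  cl <- rep(1:4, each = 10)
  expect_gt(intra_cluster_correlation(y, cl), 0.99)
  # independence -> ~0
  set.seed(51)
  y2 <- rbinom(4000, 1, 0.4)
  cl2 <- rep(1:400, each = 10)
  expect_lt(abs(intra_cluster_correlation(y2, cl2)), 0.03)
  expect_error(intra_cluster_correlation(y2, rep(1, 4000)), "clusters")
  expect_warning(intra_cluster_correlation(rep(1, 20), rep(1:2, 10)),
                 "variance")
})
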