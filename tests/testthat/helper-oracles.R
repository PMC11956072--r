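# Independent oracles, coded from the definitions with explicit scalar
# formulas and loops, deliberately avoiding the package's matrix/eigen
# implementation paths.

# Direct-formula cluster-adjusted chi-square for a 2x2 table:
# Pearson statistic on estimated proportions, linearized between-cluster
# covariance of h = p11 - p1. * p.1, scalar design effect, F reference
# with (1, K - 1) degrees of freedom.
oracle_chi2_2x2 <- function(y, g, cl, w = rep(1, length(y))) {
  y <- as.integer(as.logical(y))
  glev <- sort(unique(g))
  stopifnot(length(glev) == 2L)
  gi <- as.integer(g == glev[2])
  n <- length(y)
  N <- sum(w)
  p11 <- sum(w * (y == 1 & gi == 1)) / N
  p12 <- sum(w * (y == 1 & gi == 0)) / N
  p21 <- sum(w * (y == 0 & gi == 1)) / N
  p22 <- sum(w * (y == 0 & gi == 0)) / N
  prow1 <- p11 + p12; prow2 <- p21 + p22
  pcol1 <- p11 + p21; pcol2 <- p12 + p22
  h <- p11 - prow1 * pcol1
  X2 <- n * h^2 / (prow1 * prow2 * pcol1 * pcol2)
  # gradient of h wrt (p11, p12, p21, p22)
  grad <- c(1 - pcol1 - prow1, -pcol1, -prow1, 0)
  # multinomial covariance of the cell proportions at sample size n
  p <- c(p11, p12, p21, p22)
  V0h <- 0
  for (a in 1:4) for (b in 1:4) {
    V0h <- V0h + grad[a] * grad[b] *
      ((a == b) * p[a] - p[a] * p[b]) / n
  }
  # linearized with-replacement cluster variance of h
  zcell <- cbind(y == 1 & gi == 1, y == 1 & gi == 0,
                 y == 0 & gi == 1, y == 0 & gi == 0)
  infl <- numeric(n)
  for (i in seq_len(n)) {
    infl[i] <- sum(grad * (zcell[i, ] - p)) * w[i] / N
  }
  cls <- unique(cl)
  K <- length(cls)
  Vdh <- 0
  for (k in cls) Vdh <- Vdh + sum(infl[cl == k])^2
  Vdh <- Vdh * K / (K - 1)
  deff <- Vdh / V0h
  stat <- X2 / deff
  list(statistic = stat,
       p_value = stats::pf(stat, 1, K - 1, lower.tail = FALSE))
}

# Exact two-sided Mann-Whitney p by enumeration: U computed by explicit
# pair counting, all assignments of pooled values to the x slots.
oracle_mw_exact <- function(x, y) {
  count_u <- function(a, b) {
    u <- 0
    for (ai in a) for (bi in b) {
      u <- u + (ai > bi) + 0.5 * (ai == bi)
    }
    u
  }
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  mu <- nx * ny / 2
  u_obs <- count_u(x, y)
  sets <- utils::combn(nx + ny, nx)
  dev <- apply(sets, 2, function(ix) {
    abs(count_u(pooled[ix], pooled[-ix]) - mu)
  })
  list(U = u_obs, p_value = mean(dev >= abs(u_obs - mu) - 1e-9))
}

# Random diet table over all 29 food groups, independent Bernoulli(p).
random_diets <- function(n, p = 0.4) {
  codes <- food_group_codes()
  m <- matrix(runif(n * length(codes)) < p, n,
              dimnames = list(NULL, codes))
  tibble::as_tibble(m)
}

# Minimal respondent table wrapper around a diet table.
as_respondents <- function(diet, age_years = 30L, gender = "female",
                           n_clusters = 2L) {
  n <- nrow(diet)
  tibble::tibble(
    respondent_id = sprintf("r%04d", seq_len(n)),
    country = "Simland",
    cluster_id = sprintf("c%03d", rep_len(seq_len(n_clusters), n)),
    weight = 1,
    age_years = rep_len(age_years, n),
    gender = rep_len(gender, n),
    education = "more_than_primary",
    residence = "urban",
    wealth_quintile = 3L
  ) |> dplyr::bind_cols(diet)
}

# One sentinel food group per FGDS item: diets that vary only these ten
# groups reach every attainable (FGDS, MDD-W) combination because the
# score depends on the diet only through which items are hit.
fgds_sentinels <- function() {
  vapply(indicator_membership("FGDS")$items$groups, `[[`, character(1), 1L)
}
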