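# Design-aware descriptive statistics and comparison tests.
#
# Respondents sampled within the same primary sampling unit (cluster) are
# positively correlated, which inflates the variance of estimated
# proportions relative to simple random sampling (the design effect). The
# chi-square test of association here corrects the Pearson statistic for
# that clustering with a Rao-Scott-type adjustment: the design-based
# covariance of the estimated cell proportions is obtained by Taylor
# linearization over with-replacement cluster totals, generalized design
# effects are the eigenvalues of the multinomial-referenced covariance
# contrast, and the corrected statistic is referred to an F distribution
# (second-order Satterthwaite by default; first-order fallback when the
# design-effect matrix is rank deficient).

#' Weighted proportion with unweighted frequency
#'
#' @param flags Logical vector (no missing values), one per respondent.
#' @param weights Optional positive survey weights; default all 1.
#' @param label Optional group label carried into the output.
#' @return A one-row tibble: `group_label`, `n` (respondents), `frequency`
#'   (unweighted count of `TRUE`), `proportion_pct` (weighted percent,
#'   full precision).
#' @export
proportion_summary <- function(flags, weights = NULL, label = NA_character_) {
  if (length(flags) == 0L) stop("Empty group: no respondents.", call. = FALSE)
  if (anyNA(flags)) stop("Missing values in flags.", call. = FALSE)
  flags <- as.logical(flags)
  if (is.null(weights)) weights <- rep(1, length(flags))
  stopifnot(length(weights) == length(flags), all(weights > 0))
  tibble::tibble(
    group_label = label,
    n = length(flags),
    frequency = sum(flags),
    proportion_pct = 100 * sum(weights[flags]) / sum(weights)
  )
}

#' Median and interquartile range
#'
#' Percentiles use linear interpolation between order statistics
#' (`stats::quantile()` type 7), fixed for determinism across platforms.
#'
#' @param values Numeric vector without missing values.
#' @return A one-row tibble: `n`, `median`, `q1`, `q3`.
#' @export
median_iqr <- function(values) {
  if (length(values) == 0L) stop("Empty group: no values.", call. = FALSE)
  if (anyNA(values)) stop("Missing values.", call. = FALSE)
  q <- stats::quantile(values, probs = c(0.25, 0.5, 0.75), names = FALSE,
                       type = 7)
  tibble::tibble(n = length(values), median = q[2], q1 = q[1], q3 = q[3])
}

# Internal constructor for comparison results.
.comparison <- function(test, statistic, df, p_value, n, correction,
                        method = NA_character_, warning = NULL) {
  structure(
    list(test = test, statistic = statistic, df = df,
         p_value = min(max(p_value, 0), 1), n = n,
         correction = correction, method = method, warning = warning),
    class = "dqq_comparison")
}

#' @export
print.dqq_comparison <- function(x, ...) {
  cat(format_comparison(x), "\n")
  invisible(x)
}

#' Format a comparison result
#'
#' Renders `test, statistic (4 decimals), df, p (3 decimals, displayed as
#' "p < 0.001" below 0.001), n, correction`.
#'
#' @param x A comparison result from [cluster_adjusted_chi2()] or
#'   [mann_whitney_u()].
#' @return A single string.
#' @export
format_comparison <- function(x) {
  stopifnot(inherits(x, "dqq_comparison"))
  df_txt <- if (all(is.na(x$df))) "" else
    paste0(" (", paste(format(round(x$df, 1)), collapse = ", "), ")")
  sprintf("%s%s = %.4f, %s, n = %d [%s]",
          x$test, df_txt, x$statistic, format_p(x$p_value), x$n, x$correction)
}

#' Display-format a p-value
#'
#' @param p Numeric p-value.
#' @return `"p < 0.001"` below 0.001, else `"p = x.xxx"` (3 decimals).
#' @export
format_p <- function(p) {
  ifelse(p < 0.001, "p < 0.001", sprintf("p = %.3f", p))
}

#' Cluster-adjusted Pearson chi-square test of association
#'
#' Tests independence of a categorical outcome and a grouping variable in
#' data from a cluster sample. The uncorrected Pearson statistic is
#' computed from (optionally weighted) estimated cell proportions; the
#' Rao-Scott correction replaces the multinomial reference by the
#' design-based covariance of the cell proportions, estimated by
#' linearization over with-replacement cluster totals. By default the
#' second-order (Satterthwaite) correction is applied and the statistic is
#' referred to an F distribution with denominator degrees of freedom tied
#' to the number of clusters; the first-order (mean eigenvalue) correction
#' is used as a fallback when the design-effect matrix is rank deficient,
#' or on request.
#'
#' With one respondent per cluster and equal weights every generalized
#' design effect equals n/(n-1), so the corrected statistic is the
#' classical Pearson chi-square scaled by (n-1)/n.
#'
#' @param outcome Categorical outcome, one value per respondent (logical
#'   vectors are treated as two-level factors).
#' @param group Categorical grouping variable (>= 2 levels).
#' @param cluster Cluster (primary sampling unit) identifier per
#'   respondent; at least 2 distinct clusters are required.
#' @param weights Optional positive survey weights; default all 1.
#' @param correction `"second_order"` (default) or `"first_order"`.
#' @return A `dqq_comparison`: `test = "cluster_adjusted_chi2"`,
#'   `statistic` (the design-corrected chi-square), `df` (numerator and
#'   denominator F degrees of freedom), `p_value`, `n`, `correction`
#'   (`"rao_scott_second_order"` or `"rao_scott_first_order"`).
#' @examples
#' set.seed(1)
#' cl <- rep(1:40, each = 10)
#' g <- sample(c("a", "b"), 400, TRUE)
#' y <- runif(400) < 0.3
#' cluster_adjusted_chi2(y, g, cl)
#' @export
cluster_adjusted_chi2 <- function(outcome, group, cluster, weights = NULL,
                                  correction = c("second_order",
                                                 "first_order")) {
  correction <- match.arg(correction)
  n <- length(outcome)
  stopifnot(length(group) == n, length(cluster) == n)
  if (anyNA(outcome) || anyNA(group) || anyNA(cluster)) {
    stop("Missing values in outcome, group or cluster.", call. = FALSE)
  }
  if (is.null(weights)) weights <- rep(1, n)
  stopifnot(length(weights) == n, all(weights > 0))

  if (!is.factor(outcome)) outcome <- factor(outcome)
  if (!is.factor(group)) group <- factor(group)
  # zero-margin levels carry no information; drop with a warning
  for (v in c("outcome", "group")) {
    f <- get(v)
    empty <- levels(f)[tabulate(f, nbins = nlevels(f)) == 0L]
    if (length(empty) > 0) {
      warning("Dropping empty ", v, " level(s): ",
              paste(empty, collapse = ", "), call. = FALSE)
      assign(v, droplevels(f))
    }
  }
  R <- nlevels(outcome); C <- nlevels(group)
  if (R < 2L || C < 2L) {
    stop("Need >= 2 outcome levels and >= 2 groups with observations.",
         call. = FALSE)
  }
  clusters <- unique(cluster)
  K <- length(clusters)
  if (K < 2L) stop("Need >= 2 clusters to estimate the design variance.",
                   call. = FALSE)

  # estimated cell proportions (R x C), weighted
  N <- sum(weights)
  P <- unclass(stats::xtabs(weights ~ outcome + group)) / N
  prow <- rowSums(P); pcol <- colSums(P)
  E <- outer(prow, pcol)
  if (any(E == 0)) stop("Zero expected cell proportion.", call. = FALSE)
  X2 <- n * sum((P - E)^2 / E)

  # design covariance of vec(P) by cluster linearization (with replacement)
  z <- matrix(0, n, R * C)
  idx <- (as.integer(group) - 1L) * R + as.integer(outcome)
  z[cbind(seq_len(n), idx)] <- 1
  u <- (z - matrix(rep(as.vector(P), each = n), n)) * (weights / N)
  U <- rowsum(u, cluster)                      # K x RC cluster totals
  Vd <- K / (K - 1) * crossprod(U)             # sums to ~0 across clusters

  # multinomial reference covariance at the same effective n as X2
  p <- as.vector(P)
  V0 <- (diag(p) - tcrossprod(p)) / n

  # Jacobian of h_rc(p) = p_rc - p_r. * p_.c  (r < R, c < C) wrt vec(P)
  d <- (R - 1L) * (C - 1L)
  H <- matrix(0, d, R * C)
  row_of <- rep(seq_len(R), times = C)
  col_of <- rep(seq_len(C), each = R)
  k <- 0L
  for (cc in seq_len(C - 1L)) {
    for (rr in seq_len(R - 1L)) {
      k <- k + 1L
      H[k, ] <- (row_of == rr & col_of == cc) -
        (row_of == rr) * pcol[cc] - (col_of == cc) * prow[rr]
    }
  }
  A <- H %*% V0 %*% t(H)                       # multinomial reference
  B <- H %*% Vd %*% t(H)                       # design-based

  nu <- K - 1                                  # design degrees of freedom
  rank_ok <- qr(A)$rank == d
  lambda <- if (rank_ok) {
    Re(eigen(solve(A, B), only.values = TRUE)$values)
  } else {
    NULL
  }
  if (correction == "second_order" && rank_ok &&
      all(is.finite(lambda)) && mean(lambda) > 0) {
    lbar <- mean(lambda)
    a2 <- sum((lambda - lbar)^2) / (d * lbar^2)  # squared CV of the deffs
    Fstat <- X2 / (d * lbar)
    ndf <- d / (1 + a2)
    ddf <- nu * ndf
    p_value <- stats::pf(Fstat, ndf, ddf, lower.tail = FALSE)
    .comparison("cluster_adjusted_chi2",
                statistic = X2 / (lbar * (1 + a2)),
                df = c(ndf = ndf, ddf = ddf), p_value = p_value, n = n,
                correction = "rao_scott_second_order")
  } else {
    # first-order: mean generalized design effect via the trace
    lbar <- if (!is.null(lambda) && all(is.finite(lambda))) {
      mean(lambda)
    } else {
      Ainv <- tryCatch(solve(A), error = function(e) NULL)
      if (is.null(Ainv)) {
        sv <- svd(A)
        pos <- sv$d > max(sv$d) * 1e-12
        Ainv <- sv$v[, pos, drop = FALSE] %*%
          (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])
      }
      sum(diag(Ainv %*% B)) / d
    }
    if (!is.finite(lbar) || lbar <= 0) {
      stop("Design-effect estimate is degenerate; cannot correct.",
           call. = FALSE)
    }
    Fstat <- X2 / (d * lbar)
    p_value <- stats::pf(Fstat, d, nu * d, lower.tail = FALSE)
    .comparison("cluster_adjusted_chi2", statistic = X2 / lbar,
                df = c(ndf = d, ddf = nu * d), p_value = p_value, n = n,
                correction = "rao_scott_first_order")
  }
}

#' Mann-Whitney U rank-sum test
#'
#' Two-sided test for a location difference between two independent
#' samples. When `max(length(x), length(y)) <= 8` the exact permutation
#' distribution of U is enumerated over all assignments of the pooled
#' values (ties handled exactly); otherwise the tie-corrected normal
#' approximation is used, without continuity correction. The test is not
#' cluster-adjusted.
#'
#' @param x,y Numeric samples, both non-empty, no missing values.
#' @return A `dqq_comparison`: `test = "mann_whitney"`, `statistic` (U for
#'   `x`, counting pairs with `x > y` plus half the ties), `p_value`, `n`,
#'   `method` (`"exact_enumeration"` or `"normal_approximation"`).
#' @examples
#' mann_whitney_u(c(1, 2), c(3, 4))   # exact p = 1/3
#' @export
mann_whitney_u <- function(x, y) {
  nx <- length(x); ny <- length(y)
  if (nx == 0L || ny == 0L) stop("Both samples must be non-empty.",
                                 call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("Missing values.", call. = FALSE)
  pooled <- c(x, y)
  n <- nx + ny
  rk <- rank(pooled)
  U <- sum(rk[seq_len(nx)]) - nx * (nx + 1) / 2
  mu <- nx * ny / 2

  if (length(unique(pooled)) == 1L) {
    warning("All values identical across both samples; p = 1.",
            call. = FALSE)
    return(.comparison("mann_whitney", statistic = U, df = NA_real_,
                       p_value = 1, n = n, correction = "none",
                       method = "degenerate",
                       warning = "all values identical"))
  }

  if (max(nx, ny) <= 8L) {
    combs <- utils::combn(n, nx)
    Uperm <- colSums(matrix(rk[combs], nrow = nx)) - nx * (nx + 1) / 2
    p_value <- mean(abs(Uperm - mu) >= abs(U - mu) - 1e-9)
    method <- "exact_enumeration"
  } else {
    ties <- table(pooled)
    sigma2 <- nx * ny / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    z <- (U - mu) / sqrt(sigma2)
    p_value <- 2 * stats::pnorm(-abs(z))
    method <- "normal_approximation"
  }
  .comparison("mann_whitney", statistic = U, df = NA_real_,
              p_value = p_value, n = n, correction = "none", method = method)
}

#' Intra-cluster correlation of a binary outcome
#'
#' One-way ANOVA estimator: with between- and within-cluster mean squares
#' MSB and MSW and average cluster size correction
#' `n0 = (N - sum(m_k^2)/N) / (K - 1)`, the ICC estimate is
#' `(MSB - MSW) / (MSB + (n0 - 1) MSW)`.
#'
#' @param flags Logical or 0/1 outcome per respondent.
#' @param cluster Cluster identifier per respondent; >= 2 clusters.
#' @return ICC estimate (can be slightly negative by sampling noise);
#'   `NA` with a warning when the outcome has zero variance.
#' @export
intra_cluster_correlation <- function(flags, cluster) {
  y <- as.numeric(flags)
  stopifnot(length(cluster) == length(y))
  if (anyNA(y)) stop("Missing values.", call. = FALSE)
  cluster <- as.character(cluster)
  K <- length(unique(cluster))
  if (K < 2L) stop("Need >= 2 clusters.", call. = FALSE)
  N <- length(y)
  m <- tapply(y, cluster, length)
  ybar_k <- tapply(y, cluster, mean)
  ybar <- mean(y)
  ssb <- sum(m * (ybar_k - ybar)^2)
  ssw <- sum((y - ybar_k[cluster])^2)
  msb <- ssb / (K - 1)
  msw <- ssw / (N - K)
  n0 <- (N - sum(m^2) / N) / (K - 1)
  denom <- msb + (n0 - 1) * msw
  if (denom == 0) {
    warning("Outcome has zero variance; ICC undefined.", call. = FALSE)
    return(NA_real_)
  }
  (msb - msw) / denom
}
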