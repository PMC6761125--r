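#' @title Exact and asymptotic statistical kernels
#'
#' @description Self-contained implementations of the nonparametric and paired
#' tests used throughout the package: Wilcoxon signed-rank, Mann-Whitney U,
#' two-sample Kolmogorov-Smirnov, Fisher exact on 2x2 tables, paired t, and
#' Benjamini-Hochberg adjustment. Small problems are solved by full
#' enumeration so that every downstream p-value rests on an exactly verifiable
#' code path; larger problems use the standard normal / asymptotic
#' approximations with tie and continuity corrections.
#'
#' All kernels return a one-row tibble with columns `statistic`, `p_value`,
#' `method`, `alternative`, `exact` and `n`, so results bind directly into
#' larger result tables.
#'
#' @name stats-kernels
NULL

test_result <- function(statistic, p_value, method, alternative, exact, n) {
  tibble::tibble(
    statistic = as.numeric(statistic),
    p_value = min(max(as.numeric(p_value), 0), 1),
    method = method,
    alternative = alternative,
    exact = exact,
    n = as.integer(n)
  )
}

match_alternative <- function(alternative) {
  match.arg(alternative, c("two_sided", "greater", "less"))
}

#' Wilcoxon signed-rank test
#'
#' One-sample (or paired, via `x - y` supplied by the caller) signed-rank
#' test. Zero differences are dropped, as in the classical procedure. For
#' `n <= exact_max` (zeros removed) the null distribution of the rank sum of
#' positive differences is computed by dynamic programming over all 2^n sign
#' assignments, conditioning on the observed (mid)ranks, so ties are handled
#' exactly. Above that, a normal approximation with tie correction and
#' continuity correction is used.
#'
#' @param x numeric vector of differences.
#' @param alternative `"two_sided"`, `"greater"` (positive location) or
#'   `"less"`.
#' @param mu null location, default 0.
#' @param exact_max largest n for which the exact distribution is enumerated.
#' @return one-row tibble (`statistic` is V, the positive-rank sum).
#' @export
wilcoxon_signed_rank <- function(x, alternative = "two_sided", mu = 0,
                                 exact_max = 25) {
  alternative <- match_alternative(alternative)
  d <- x[!is.na(x)] - mu
  n_zero <- sum(d == 0)
  if (n_zero > 0) d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    warning("all differences are zero; returning p = 1")
    return(test_result(NA_real_, 1, "Wilcoxon signed-rank", alternative, TRUE, 0L))
  }
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  if (n <= exact_max) {
    # DP over doubled ranks (midranks are multiples of 1/2)
    r2 <- as.integer(round(2 * r))
    tot <- sum(r2)
    counts <- numeric(tot + 1)  # index w+1 holds #assignments with 2V == w
    counts[1] <- 1
    for (ri in r2) {
      shifted <- c(rep(0, ri), counts[seq_len(tot + 1 - ri)])
      counts <- counts + shifted
    }
    probs <- counts / 2^n
    v2 <- round(2 * v)
    p_ge <- sum(probs[(v2 + 1):(tot + 1)])
    p_le <- sum(probs[1:(v2 + 1)])
    p <- switch(alternative,
      greater = p_ge,
      less = p_le,
      two_sided = min(1, 2 * min(p_ge, p_le))
    )
    return(test_result(v, p, "Wilcoxon signed-rank (exact)", alternative, TRUE, n))
  }
  mu_v <- n * (n + 1) / 4
  tie_tab <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tie_tab^3 - tie_tab) / 48
  z_num <- v - mu_v
  cc <- switch(alternative,
    greater = -0.5, less = 0.5,
    two_sided = -sign(z_num) * 0.5
  )
  z <- (z_num + cc) / sqrt(sigma2)
  p <- switch(alternative,
    greater = stats::pnorm(z, lower.tail = FALSE),
    less = stats::pnorm(z),
    two_sided = 2 * stats::pnorm(abs(z), lower.tail = FALSE)
  )
  test_result(v, min(p, 1), "Wilcoxon signed-rank (normal approx.)",
              alternative, FALSE, n)
}

#' Mann-Whitney U test
#'
#' Rank-sum comparison of two independent samples. Exact when
#' `min(n, m) <= exact_max` and there are no ties (enumeration of all
#' choose(n+m, n) arrangements); otherwise normal approximation with
#' midranks, tie correction and continuity correction.
#'
#' @param x,y numeric samples.
#' @param alternative `"greater"` means x is stochastically larger than y.
#' @param exact_max exact-enumeration bound on the smaller sample size.
#' @return one-row tibble (`statistic` is U for `x`).
#' @export
mann_whitney_u <- function(x, y, alternative = "two_sided", exact_max = 8) {
  alternative <- match_alternative(alternative)
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n <- length(x); m <- length(y)
  if (n == 0 || m == 0) stop("both samples must be non-empty")
  r_all <- rank(c(x, y))
  u <- sum(r_all[seq_len(n)]) - n * (n + 1) / 2
  has_ties <- anyDuplicated(c(x, y)) > 0
  if (!has_ties && min(n, m) <= exact_max) {
    # enumerate rank sets of the x-sample under the null
    combs <- utils::combn(n + m, n)
    u_null <- colSums(matrix(combs, nrow = n)) - n * (n + 1) / 2
    p_ge <- mean(u_null >= u)
    p_le <- mean(u_null <= u)
    p <- switch(alternative,
      greater = p_ge, less = p_le,
      two_sided = min(1, 2 * min(p_ge, p_le))
    )
    return(test_result(u, p, "Mann-Whitney U (exact)", alternative, TRUE, n + m))
  }
  mu_u <- n * m / 2
  nm <- n + m
  tie_tab <- table(r_all)
  sigma2 <- n * m / 12 * ((nm + 1) - sum(tie_tab^3 - tie_tab) / (nm * (nm - 1)))
  z_num <- u - mu_u
  cc <- switch(alternative,
    greater = -0.5, less = 0.5,
    two_sided = -sign(z_num) * 0.5
  )
  z <- if (sigma2 > 0) (z_num + cc) / sqrt(sigma2) else 0
  p <- switch(alternative,
    greater = stats::pnorm(z, lower.tail = FALSE),
    less = stats::pnorm(z),
    two_sided = if (z_num == 0) 1 else 2 * stats::pnorm(abs(z), lower.tail = FALSE)
  )
  test_result(u, min(p, 1), "Mann-Whitney U (normal approx.)",
              alternative, FALSE, n + m)
}

# Kolmogorov asymptotic survival function Q(lambda) = 2 sum (-1)^(k-1) exp(-2 k^2 lambda^2)
kolmogorov_sf <- function(lambda) {
  if (lambda < 0.05) return(1)
  k <- 1:100
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))
  min(max(p, 0), 1)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' D statistic (sup of ECDF difference) with the asymptotic Kolmogorov
#' p-value.
#'
#' @param x,y numeric samples.
#' @return one-row tibble (`statistic` is D).
#' @export
ks_two_sample <- function(x, y) {
  x <- sort(x[!is.na(x)]); y <- sort(y[!is.na(y)])
  n <- length(x); m <- length(y)
  if (n == 0 || m == 0) stop("both samples must be non-empty")
  pts <- sort(unique(c(x, y)))
  fx <- stats::ecdf(x)(pts)
  fy <- stats::ecdf(y)(pts)
  d <- max(abs(fx - fy))
  lambda <- sqrt(n * m / (n + m)) * d
  test_result(d, kolmogorov_sf(lambda), "Kolmogorov-Smirnov (asymptotic)",
              "two_sided", FALSE, n + m)
}

#' Fisher exact test on a 2x2 table
#'
#' Hypergeometric enumeration. Two-sided p sums all table probabilities not
#' exceeding that of the observed table (standard convention, with a small
#' relative tolerance against floating-point noise).
#'
#' @param tab 2x2 matrix or length-4 vector (a, c, b, d column-major).
#' @param alternative `"greater"` tests enrichment of the (1,1) cell.
#' @return one-row tibble (`statistic` is the sample odds ratio, ad/bc).
#' @export
fisher_exact_2x2 <- function(tab, alternative = "two_sided") {
  alternative <- match_alternative(alternative)
  tab <- matrix(as.numeric(tab), 2, 2)
  if (any(tab < 0) || any(tab != round(tab))) stop("table must hold non-negative counts")
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  m1 <- a + b; m2 <- c + d; k <- a + c
  or <- (a * d) / (b * c)
  if (m1 == 0 || m2 == 0 || k == 0 || (b + d) == 0) {
    warning("zero margin in 2x2 table; p = 1")
    return(test_result(or, 1, "Fisher exact", alternative, TRUE, sum(tab)))
  }
  support <- max(0, k - m2):min(k, m1)
  probs <- stats::dhyper(support, m1, m2, k)
  p_obs <- stats::dhyper(a, m1, m2, k)
  p <- switch(alternative,
    greater = sum(probs[support >= a]),
    less = sum(probs[support <= a]),
    two_sided = sum(probs[probs <= p_obs * (1 + 1e-7)])
  )
  test_result(or, min(p, 1), "Fisher exact", alternative, TRUE, sum(tab))
}

#' Paired Student's t test
#'
#' t on the paired differences. When the differences are constant the test is
#' degenerate: identical pairs return p = 1 by convention, a constant nonzero
#' difference returns p = 0 with a warning.
#'
#' @param x,y paired numeric vectors.
#' @param alternative sidedness for the mean difference x - y.
#' @return one-row tibble (`statistic` is t; `n` the number of pairs).
#' @export
paired_t <- function(x, y, alternative = "two_sided") {
  alternative <- match_alternative(alternative)
  keep <- !is.na(x) & !is.na(y)
  d <- x[keep] - y[keep]
  n <- length(d)
  if (n < 2) stop("need at least 2 complete pairs")
  s <- stats::sd(d)
  if (s == 0) {
    if (mean(d) == 0) {
      return(test_result(0, 1, "paired t", alternative, FALSE, n))
    }
    warning("constant nonzero differences; p = 0")
    return(test_result(sign(mean(d)) * Inf, 0, "paired t", alternative, FALSE, n))
  }
  t_stat <- mean(d) / (s / sqrt(n))
  p <- switch(alternative,
    greater = stats::pt(t_stat, n - 1, lower.tail = FALSE),
    less = stats::pt(t_stat, n - 1),
    two_sided = 2 * stats::pt(abs(t_stat), n - 1, lower.tail = FALSE)
  )
  test_result(t_stat, p, "paired t", alternative, FALSE, n)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment: monotone-enforced, capped at 1, permutation
#' equivariant. NA p-values propagate as NA and do not count toward the
#' family size.
#'
#' @param p numeric vector of p-values.
#' @return adjusted p-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  out <- rep(NA_real_, length(p))
  ok <- which(!is.na(p))
  pv <- p[ok]
  m <- length(pv)
  if (m == 0) return(out)
  o <- order(pv, decreasing = TRUE)
  ro <- order(o)
  out[ok] <- pmin(1, cummin(m / (m:1) * pv[o]))[ro]
  out
}
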