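#' Paired Wilcoxon signed-rank test
#'
#' Two-sided p-value for paired samples. Zero differences are discarded
#' (classic Wilcoxon policy; set `zero_method = "pratt"` to keep them in the
#' ranking). The exact distribution is used for n <= 25 untied differences
#' after zero removal; otherwise the normal approximation with tie correction
#' and continuity correction.
#'
#' @param x,y Paired numeric vectors of equal length (`y` may be omitted to
#'   test differences `x` against zero).
#' @param zero_method `"wilcox"` (discard zeros) or `"pratt"`.
#' @return Two-sided p-value; 1 when all differences are zero.
#' @export
wilcoxon_signed_rank <- function(x, y = NULL, zero_method = c("wilcox", "pratt")) {
  zero_method <- match.arg(zero_method)
  if (!is.null(y) && length(x) != length(y))
    stop("x and y must have equal length")
  d <- if (is.null(y)) x else x - y
  if (length(d) == 0L) stop("no observations")
  if (all(d == 0)) return(1)
  if (zero_method == "wilcox") {
    d <- d[d != 0]
    n <- length(d)
    exact <- n <= 25 && !any(duplicated(abs(d)))
    p <- suppressWarnings(stats::wilcox.test(d, exact = exact,
                                             correct = TRUE)$p.value)
    return(min(1, p))
  }
  # Pratt: rank zeros with the rest, then drop their contribution; normal
  # approximation with tie correction.
  n <- length(d)
  r <- rank(abs(d))
  wplus <- sum(r[d > 0])
  nz <- sum(d == 0)
  r0 <- r[d == 0]
  mu <- (n * (n + 1) / 2 - nz * (nz + 1) / 2) / 2
  ties <- table(r)
  sig2 <- n * (n + 1) * (2 * n + 1) / 24 -
    nz * (nz + 1) * (2 * nz + 1) / 24 -
    sum(ties^3 - ties) / 48
  z <- (wplus - mu) / sqrt(sig2)
  min(1, 2 * stats::pnorm(-abs(z)))
}

#' Fisher's method for combining independent p-values
#'
#' @param pvals Numeric vector of p-values in `(0, 1]`.
#' @return A list with `chi2` (`-2 * sum(log(p))`), `df` (`2k`) and `p`
#'   (upper-tail chi-square probability).
#' @export
fishers_combined <- function(pvals) {
  if (length(pvals) == 0L) stop("no p-values supplied")
  if (any(pvals <= 0) || any(pvals > 1))
    stop("p-values must lie in (0, 1]; clamp zeros at the machine minimum first")
  chi2 <- -2 * sum(log(pvals))
  df <- 2L * length(pvals)
  list(chi2 = chi2, df = df,
       p = stats::pchisq(chi2, df = df, lower.tail = FALSE))
}

#' Percentile bootstrap confidence interval of the mean
#'
#' Resamples with replacement `B` times under an explicit seed (the caller's
#' RNG state is untouched) and returns the percentile interval of the
#' resampled means, matching the smean.cl.boot convention with B = 500.
#'
#' @param values Numeric vector.
#' @param B Number of bootstrap resamples.
#' @param confidence Confidence level.
#' @param seed Integer seed (required for reproducibility).
#' @return Named numeric vector `c(mean, low, high)`.
#' @export
bootstrap_mean_ci <- function(values, B = 500, confidence = 0.95, seed) {
  if (length(values) == 0L) stop("values must be non-empty")
  if (missing(seed)) stop("seed is required")
  n <- length(values)
  means <- with_seed(seed, {
    rowMeans(matrix(sample(values, n * B, replace = TRUE), nrow = B))
  })
  alpha <- (1 - confidence) / 2
  ci <- unname(stats::quantile(means, c(alpha, 1 - alpha)))
  c(mean = mean(values), low = ci[1], high = ci[2])
}

#' Cohen's d with a normal-theory confidence interval
#'
#' Standardized mean difference `(mean(a) - mean(b)) / s_pooled` with the
#' pooled unbiased standard deviation, and the large-sample variance
#' `Var(d) = (n_a + n_b) / (n_a n_b) + d^2 / (2 (n_a + n_b))` for the CI.
#' With few groups (e.g. two groups of 15 cohort means) the interval is
#' intentionally wide.
#'
#' @param a,b Numeric vectors (each of length >= 2).
#' @param confidence Confidence level.
#' @return Named numeric vector `c(d, low, high)`.
#' @export
cohens_d <- function(a, b, confidence = 0.95) {
  na <- length(a); nb <- length(b)
  if (na < 2 || nb < 2) stop("each group needs at least 2 values")
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  if (sp2 == 0) stop("zero pooled standard deviation")
  d <- (mean(a) - mean(b)) / sqrt(sp2)
  vd <- (na + nb) / (na * nb) + d^2 / (2 * (na + nb))
  z <- stats::qnorm((1 + confidence) / 2)
  c(d = d, low = d - z * sqrt(vd), high = d + z * sqrt(vd))
}

#' Exact binomial sign test
#'
#' One-sided: `P[X >= k]` under Binomial(n, p0). Two-sided: twice the smaller
#' tail (`P[X <= k]` vs `P[X >= k]`), capped at 1.
#'
#' @param k Number of successes.
#' @param n Number of trials.
#' @param p0 Null success probability in `(0, 1)`.
#' @param sided `"one"` or `"two"`.
#' @return Exact tail probability.
#' @export
binomial_sign_test <- function(k, n, p0 = 0.5, sided = c("one", "two")) {
  sided <- match.arg(sided)
  if (p0 <= 0 || p0 >= 1) stop("p0 must be in (0, 1)")
  if (k < 0 || k > n) stop("k must be in [0, n]")
  upper <- stats::pbinom(k - 1, n, p0, lower.tail = FALSE)
  if (sided == "one") return(upper)
  lower <- stats::pbinom(k, n, p0)
  min(1, 2 * min(lower, upper))
}

#' Mann-Whitney U (rank-sum) test
#'
#' Two-sided p-value; exact for small untied samples, tie-corrected normal
#' approximation with continuity correction otherwise.
#'
#' @param a,b Numeric vectors.
#' @return Two-sided p-value.
#' @export
mann_whitney_u <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) stop("both groups must be non-empty")
  exact <- length(a) < 50 && length(b) < 50 && !any(duplicated(c(a, b)))
  min(1, suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                             correct = TRUE)$p.value))
}
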