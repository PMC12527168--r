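# Rank-based tests are implemented from first principles (midranks, exact
# enumeration at small n, normal approximation with tie and continuity
# corrections otherwise) so that every downstream statistic in the package is
# auditable against brute-force enumeration.

new_htest <- function(statistic, p_value, method, alternative, n,
                      estimate = NA_real_) {
  structure(
    list(statistic = unname(statistic), p_value = unname(p_value),
         method = method, alternative = alternative, n = n,
         estimate = estimate),
    class = "zw_htest"
  )
}

#' @export
print.zw_htest <- function(x, ...) {
  cat(sprintf("%s\nstatistic = %.6g, p = %.4g (alternative: %s; n = %s)\n",
              x$method, x$statistic, x$p_value, x$alternative,
              paste(x$n, collapse = ", ")))
  invisible(x)
}

#' @rdname zw_tidiers
#' @export
tidy.zw_htest <- function(x, ...) {
  tibble(statistic = x$statistic, p.value = x$p_value, method = x$method,
         alternative = x$alternative, n1 = x$n[1],
         n2 = if (length(x$n) > 1) x$n[2] else NA_integer_)
}

#' @rdname zw_tidiers
#' @export
glance.zw_htest <- function(x, ...) tidy(x, ...)

check_alternative <- function(alternative) {
  match.arg(alternative, c("two_sided", "less", "greater"))
}

one_minus_cdf <- function(dist, q) {
  # P(X >= q) for a tabulated discrete distribution
  sum(dist$prob[dist$value >= q - 1e-9])
}
cdf_at <- function(dist, q) sum(dist$prob[dist$value <= q + 1e-9])

p_from_dist <- function(dist, stat, alternative) {
  switch(alternative,
    less = cdf_at(dist, stat),
    greater = one_minus_cdf(dist, stat),
    two_sided = min(1, 2 * min(cdf_at(dist, stat), one_minus_cdf(dist, stat)))
  )
}

# exact null distribution of the Mann-Whitney U for x (n1) vs y (n2), no ties
exact_u_distribution <- function(n1, n2) {
  n <- n1 + n2
  combos <- utils::combn(n, n1)
  u <- colSums(combos) - n1 * (n1 + 1) / 2
  tab <- table(u)
  tibble(value = as.numeric(names(tab)),
         prob = as.numeric(tab) / ncol(combos))
}

# exact null distribution of the signed-rank statistic W+ for n untied |d|
exact_wplus_distribution <- function(n) {
  # distribution of subset sums of {1..n} via polynomial convolution
  probs <- 1
  for (r in seq_len(n)) {
    padded <- c(probs, numeric(r))
    probs <- (padded + c(numeric(r), probs)) / 2
  }
  tibble(value = seq_along(probs) - 1, prob = probs)
}

p_normal_approx <- function(z0, sigma, alternative, continuity) {
  if (sigma == 0) {
    return(1)  # degenerate null (e.g. all observations tied): no evidence
  }
  cc <- if (continuity) {
    switch(alternative, two_sided = sign(z0) * 0.5, greater = 0.5, less = -0.5)
  } else 0
  z <- (z0 - cc) / sigma
  switch(alternative,
    less = pnorm(z),
    greater = pnorm(z, lower.tail = FALSE),
    two_sided = min(1, 2 * min(pnorm(z), pnorm(z, lower.tail = FALSE)))
  )
}

#' Wilcoxon-Mann-Whitney rank-sum test
#'
#' Two-sample rank-sum test on the Mann-Whitney U statistic (for the first
#' sample), with midranks for ties. The null distribution is enumerated
#' exactly when `length(x) + length(y) <= 12` and there are no ties; otherwise
#' a normal approximation with tie-corrected variance and optional continuity
#' correction is used. `alternative = "greater"` means `x` tends to exceed
#' `y`.
#'
#' @param x,y Numeric samples.
#' @param alternative One of `"two_sided"`, `"less"`, `"greater"`.
#' @param continuity Apply the 0.5 continuity correction in the normal
#'   approximation (default `TRUE`).
#' @return A `zw_htest` object (see [tidy.zw_htest()]).
#' @export
#' @examples
#' rank_sum_test(c(1, 2, 3), c(4, 5, 6))  # exact, p = 0.1
rank_sum_test <- function(x, y, alternative = "two_sided", continuity = TRUE) {
  alternative <- check_alternative(alternative)
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 1 || length(y) < 1) abort("both samples must be non-empty")
  if (anyNA(x) || anyNA(y)) abort("samples must not contain NA")
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- any(duplicated(c(x, y)))
  if (n <= 12 && !ties) {
    p <- p_from_dist(exact_u_distribution(n1, n2), u, alternative)
    method <- "Wilcoxon rank-sum test (exact)"
  } else {
    tie_tab <- table(r)
    sigma2 <- n1 * n2 / 12 *
      ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
    p <- p_normal_approx(u - n1 * n2 / 2, sqrt(sigma2), alternative, continuity)
    method <- paste0("Wilcoxon rank-sum test (normal approximation",
                     if (continuity) ", continuity corrected", ")")
  }
  new_htest(u, p, method, alternative, c(n1 = n1, n2 = n2))
}

#' Wilcoxon signed-rank test
#'
#' One-sample (or paired-difference) signed-rank test of `d` against zero on
#' the positive-rank-sum statistic W+, with midranks for tied `|d|`. Zeros
#' are dropped first. The null distribution is enumerated exactly over all
#' sign assignments when the remaining `n <= 12` and `|d|` has no ties;
#' otherwise a normal approximation with tie-corrected variance and optional
#' continuity correction is used.
#'
#' @param d Numeric vector of differences (or values to test against 0).
#' @inheritParams rank_sum_test
#' @return A `zw_htest` object.
#' @export
#' @examples
#' signed_rank_test(c(1, 2, 3), alternative = "greater")  # W+ = 6, p = 0.125
signed_rank_test <- function(d, alternative = "two_sided", continuity = TRUE) {
  alternative <- check_alternative(alternative)
  d <- as.numeric(d)
  if (anyNA(d)) abort("`d` must not contain NA")
  d <- d[d != 0]
  n <- length(d)
  if (n < 1) abort("no nonzero differences")
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  ties <- any(duplicated(abs(d)))
  if (n <= 12 && !ties) {
    p <- p_from_dist(exact_wplus_distribution(n), w, alternative)
    method <- "Wilcoxon signed-rank test (exact)"
  } else {
    tie_tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tie_tab^3 - tie_tab) / 48
    p <- p_normal_approx(w - n * (n + 1) / 4, sqrt(sigma2), alternative,
                         continuity)
    method <- paste0("Wilcoxon signed-rank test (normal approximation",
                     if (continuity) ", continuity corrected", ")")
  }
  new_htest(w, p, method, alternative, c(n = n))
}

#' Multiple-testing adjustment
#'
#' Bonferroni (`min(1, m * p)`) or Benjamini-Hochberg step-up adjustment with
#' monotonicity enforcement. Input order is preserved.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (NA allowed, passed
#'   through).
#' @param method `"bonferroni"` or `"bh"`.
#' @param m Number of comparisons; defaults to `length(p)` but may be larger
#'   when only a subset of a fixed comparison family was computed.
#' @return Adjusted p-values, same length and order as `p`.
#' @export
adjust_pvalues <- function(p, method = c("bonferroni", "bh"), m = length(p)) {
  method <- match.arg(method)
  p <- as.numeric(p)
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) abort("p-values must lie in [0, 1]")
  if (m < sum(ok)) abort("`m` must be at least the number of p-values")
  out <- p
  if (method == "bonferroni") {
    out[ok] <- pmin(1, m * p[ok])
  } else {
    pp <- p[ok]
    k <- length(pp)
    o <- order(pp, decreasing = TRUE)
    ro <- order(o)
    # ranks within the family of size m: the k observed p-values occupy the
    # top-k ranks only when k == m; with k < m the BH denominator still uses
    # the observed ranks 1..k (standard subset behaviour)
    adj <- pmin(1, cummin(m / k:1 * pp[o]))[ro]
    out[ok] <- adj
  }
  out
}

#' Counts-per-million normalization
#'
#' @param counts Non-negative numeric vector with a positive sum.
#' @return `counts * 1e6 / sum(counts)`; sums to 1e6.
#' @export
cpm_normalize <- function(counts) {
  counts <- as.numeric(counts)
  if (any(counts < 0, na.rm = TRUE)) abort("counts must be non-negative")
  total <- sum(counts)
  if (!is.finite(total) || total <= 0) {
    abort("cannot CPM-normalize an all-zero count vector")
  }
  counts * 1e6 / total
}

#' Coefficient of variation
#'
#' Sample standard deviation (n - 1 denominator) divided by the mean.
#'
#' @param v Numeric vector, length >= 2.
#' @return `sd(v) / mean(v)`, or `NA` with a warning when the mean is zero.
#' @export
coefficient_of_variation <- function(v) {
  v <- as.numeric(v)
  if (length(v) < 2) abort("need at least 2 values for a CV")
  m <- mean(v)
  if (m == 0) {
    warn("mean is zero; CV undefined")
    return(NA_real_)
  }
  sd(v) / m
}

#' Pearson product-moment correlation
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return Correlation in `[-1, 1]`, or `NA` with a warning when either
#'   vector has zero variance.
#' @export
pearson_r <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) abort("`x` and `y` must have equal length")
  if (length(x) < 3) abort("need at least 3 pairs")
  cx <- x - mean(x); cy <- y - mean(y)
  sx <- sqrt(sum(cx^2)); sy <- sqrt(sum(cy^2))
  if (sx == 0 || sy == 0) {
    warn("zero variance; correlation undefined")
    return(NA_real_)
  }
  max(-1, min(1, sum(cx * cy) / (sx * sy)))
}
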