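# Self-contained statistical kernel. The proportion-equality tests are
# Yates-corrected chi-square tests on the contingency table (prop.test-style);
# this is the construction that reproduces the reference association p-value
# 0.03143 (20/25 vs 15/31) and the orientation-bias "P = 0.5" (25/56 vs 0.5),
# both asserted in the acceptance suite.

#' Two-proportion equality test
#'
#' Compares x1/n1 with x2/n2. With `continuity = TRUE` (default) this is the
#' chi-square test on the 2x2 table with Yates continuity correction, the
#' correction magnitude capped so the corrected deviation stays >= 0; the
#' two-sided p comes from the chi-square(1) tail and the statistic reported is
#' the corrected chi-square. With `continuity = FALSE` it is the pooled
#' two-sample z-test (statistic z; identical p to the uncorrected chi-square).
#'
#' @param x1,n1,x2,n2 successes and totals of the two samples.
#' @param continuity apply the Yates correction?
#' @return a [test_result()].
#' @export
two_proportion_test <- function(x1, n1, x2, n2, continuity = TRUE) {
  stopifnot(x1 >= 0, x2 >= 0, x1 <= n1, x2 <= n2, n1 >= 1 || n2 >= 1)
  n <- n1 + n2
  s <- x1 + x2
  if (n == 0 || n1 == 0 || n2 == 0 || s == 0 || s == n) {
    return(test_result(NA_real_, NA_real_,
                       "two-proportion chi-square (degenerate table)",
                       degenerate = TRUE))
  }
  if (continuity) {
    obs <- c(x1, n1 - x1, x2, n2 - x2)
    exp <- c(n1 * s / n, n1 * (n - s) / n, n2 * s / n, n2 * (n - s) / n)
    corr <- min(0.5, abs(obs[1] - exp[1]))
    chi2 <- sum((abs(obs - exp) - corr)^2 / exp)
    test_result(chi2, stats::pchisq(chi2, df = 1, lower.tail = FALSE),
                "two-proportion chi-square, Yates-corrected")
  } else {
    pp <- s / n
    z <- (x1 / n1 - x2 / n2) / sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
    test_result(z, 2 * stats::pnorm(-abs(z)), "two-proportion pooled z-test")
  }
}

#' One-proportion test against a fixed probability
#'
#' Chi-square(1) test of H0: p = p0, Yates-corrected when `continuity = TRUE`
#' (correction capped at the raw deviation, so an exact match gives p = 1).
#' Uncorrected form reports the z statistic.
#'
#' @param x,n successes and total.
#' @param p0 null proportion, strictly inside (0, 1).
#' @param continuity apply the Yates correction?
#' @return a [test_result()].
#' @export
one_proportion_test <- function(x, n, p0 = 0.5, continuity = TRUE) {
  stopifnot(x >= 0, x <= n, p0 > 0, p0 < 1)
  if (n == 0) {
    return(test_result(NA_real_, NA_real_,
                       "one-proportion chi-square (degenerate)", degenerate = TRUE))
  }
  dev <- abs(x - n * p0)
  if (continuity) {
    corr <- min(0.5, dev)
    chi2 <- (dev - corr)^2 / (n * p0 * (1 - p0))
    test_result(chi2, stats::pchisq(chi2, df = 1, lower.tail = FALSE),
                "one-proportion chi-square, Yates-corrected")
  } else {
    z <- (x / n - p0) / sqrt(p0 * (1 - p0) / n)
    test_result(z, 2 * stats::pnorm(-abs(z)), "one-proportion z-test")
  }
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum test. The exact method uses the null distribution of U
#' (valid without ties) and is auto-selected when `min(n, m) <= 12` and the
#' pooled sample is tie-free; with ties the exact request falls back to the
#' normal approximation with a warning. The normal approximation uses the
#' tie-corrected variance and a 0.5 continuity correction.
#'
#' @param a,b numeric samples (non-empty).
#' @param method `"auto"`, `"exact"` or `"normal_approx"`.
#' @return a [test_result()]; the statistic is U for sample `a`.
#' @export
mann_whitney <- function(a, b, method = c("auto", "exact", "normal_approx")) {
  method <- match.arg(method)
  if (!length(a) || !length(b)) stop("both samples must be non-empty")
  n <- length(a); m <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  u <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  ties <- anyDuplicated(pooled) > 0
  if (method == "auto") {
    method <- if (!ties && min(n, m) <= 12) "exact" else "normal_approx"
  }
  if (method == "exact" && ties) {
    warning("ties present; exact Mann-Whitney falling back to normal approximation")
    method <- "normal_approx"
  }
  if (method == "exact") {
    p <- if (u > n * m / 2) {
      2 * stats::pwilcox(u - 1, n, m, lower.tail = FALSE)
    } else {
      2 * stats::pwilcox(u, n, m)
    }
    test_result(u, min(1, p), "Mann-Whitney U, exact")
  } else {
    nt <- n + m
    tie_counts <- table(pooled)
    sigma2 <- n * m / 12 *
      ((nt + 1) - sum(tie_counts^3 - tie_counts) / (nt * (nt - 1)))
    if (sigma2 <= 0) {
      return(test_result(u, 1, "Mann-Whitney U, normal approximation (all tied)"))
    }
    dev <- abs(u - n * m / 2)
    z <- max(0, dev - 0.5) / sqrt(sigma2)
    test_result(u, min(1, 2 * stats::pnorm(-z)),
                "Mann-Whitney U, normal approximation")
  }
}

#' Spearman rank correlation
#'
#' Midrank-tie rank correlation; the p-value uses the t approximation with
#' n - 2 degrees of freedom (two-sided). Perfectly correlated input gives
#' p = 0 under this approximation; constant input is flagged degenerate.
#'
#' @param x,y equal-length numeric vectors, length >= 3.
#' @return a [test_result()] with the correlation as statistic.
#' @export
spearman_test <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3) stop("need at least 3 observations")
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    return(test_result(NA_real_, NA_real_,
                       "Spearman correlation (constant input)", degenerate = TRUE))
  }
  r <- stats::cor(rx, ry)
  if (abs(r) >= 1) {
    p <- 0
  } else {
    t <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(t), df = n - 2)
  }
  test_result(r, p, "Spearman rank correlation")
}

#' Serialize test results to a data.frame
#'
#' One row per test: statistic, p, stars, method — the layout used in the
#' pipeline's TSV reports.
#'
#' @param ... [test_result()] objects (optionally named).
#' @return a data.frame.
#' @export
tests_to_table <- function(...) {
  tests <- list(...)
  nm <- names(tests)
  if (is.null(nm)) nm <- rep("", length(tests))
  do.call(rbind, lapply(seq_along(tests), function(i) {
    t <- tests[[i]]
    data.frame(label = nm[i], statistic = t$statistic, p_value = t$p_value,
               stars = t$stars, method = t$method, stringsAsFactors = FALSE)
  }))
}
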