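# Nonparametric summaries and tests used by the reporting tables.
#
# Quantiles use the weighted-average (n+1)p definition (quantile type 6),
# matching the convention of mainstream commercial statistics packages.
# Group comparisons with fewer than two observations in any group are
# reported "not applicable" rather than as a p-value.

#' Median and interquartile range
#'
#' Computes the median and the first/third quartiles with the
#' weighted-average \eqn{(n+1)p} quantile definition (type 6).
#'
#' @param values Numeric vector with at least one non-missing value.
#' @return Named numeric vector `c(median, q1, q3)`.
#' @export
#' @examples
#' median_iqr(c(1, 2, 3, 4, 5)) # 3, 1.5, 4.5
median_iqr <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 1) stop("need at least one value", call. = FALSE)
  q <- stats::quantile(values, probs = c(0.5, 0.25, 0.75), type = 6,
                       names = FALSE)
  c(median = q[1], q1 = q[2], q3 = q[3])
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum test. The p-value is exact (by enumeration of rank
#' assignments) when the combined sample size is at most 12 and there are no
#' ties; otherwise the normal approximation with tie-corrected variance and
#' continuity correction is used. Groups with fewer than two observations
#' are not testable and are flagged not applicable.
#'
#' @param a,b Numeric samples.
#' @param method `"auto"` (default branch rule), `"exact"` or `"normal"`.
#' @param correct Apply the continuity correction in the normal branch.
#' @return List with `applicable`, `U` (midrank U statistic for `a`), `p`
#'   (two-sided) and `method` used.
#' @export
#' @examples
#' mann_whitney_u(c(1, 2), c(3, 4)) # U = 0, p = 1/3
mann_whitney_u <- function(a, b, method = c("auto", "exact", "normal"),
                           correct = TRUE) {
  method <- match.arg(method)
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2) {
    return(list(applicable = FALSE, U = NA_real_, p = NA_real_,
                method = "n.a."))
  }
  ties <- anyDuplicated(c(a, b)) > 0
  if (method == "auto") {
    method <- if (length(a) + length(b) <= 12 && !ties) "exact" else "normal"
  }
  if (method == "exact" && ties) {
    stop("exact enumeration is not defined in the presence of ties",
         call. = FALSE)
  }
  res <- if (method == "exact") {
    stats::wilcox.test(a, b, exact = TRUE)
  } else {
    suppressWarnings(stats::wilcox.test(a, b, exact = FALSE, correct = correct))
  }
  list(applicable = TRUE, U = unname(res$statistic), p = res$p.value,
       method = method)
}

#' Kruskal-Wallis test for k independent samples
#'
#' Tie-corrected H statistic with the chi-squared tail on k - 1 degrees of
#' freedom. Needs at least two groups with at least two observations each;
#' otherwise flagged not applicable.
#'
#' @param groups List of numeric samples.
#' @return List with `applicable`, `H`, `df`, `p`.
#' @export
#' @examples
#' kruskal_wallis(list(c(1, 2), c(3, 4), c(5, 6))) # H = 32/7
kruskal_wallis <- function(groups) {
  groups <- lapply(groups, function(g) g[!is.na(g)])
  if (length(groups) < 2 || any(lengths(groups) < 2)) {
    return(list(applicable = FALSE, H = NA_real_, df = NA_real_,
                p = NA_real_))
  }
  values <- unlist(groups)
  labels <- factor(rep(seq_along(groups), lengths(groups)))
  res <- stats::kruskal.test(values, labels)
  list(applicable = TRUE, H = unname(res$statistic),
       df = unname(res$parameter), p = res$p.value)
}
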