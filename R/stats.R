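#' Mann-Whitney U test for two independent samples
#'
#' Rank-sum test with midranks for ties. The p-value is exact (by
#' enumeration of arrangements) when the combined sample size is at most
#' 16 and there are no ties; otherwise the normal approximation with tie
#' and continuity corrections is used. The reported U is the number of
#' (a, b) pairs with a > b, counting ties as 1/2, i.e. the statistic for
#' the first sample.
#'
#' @param a,b numeric vectors (both nonempty).
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`,
#'   relative to the first sample.
#' @return list with `U`, `p_value`, `method` (`"exact"` or
#'   `"normal_approx"`), `n_a`, `n_b`.
#' @export
mann_whitney <- function(a, b, alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) == 0 || length(b) == 0) stop("both samples must be nonempty", call. = FALSE)
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- (length(a) + length(b) <= 16) && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, alternative = alternative, exact = exact,
                       correct = TRUE)
  )
  list(U = unname(wt$statistic), p_value = wt$p.value,
       method = if (exact) "exact" else "normal_approx",
       n_a = length(a), n_b = length(b))
}

#' Boxplot summary statistics
#'
#' Median, quartiles (linear interpolation between order statistics,
#' R's default type-7 convention), minimum, maximum and n — the
#' distributional summary used to report per-field imaging measurements.
#'
#' @param values nonempty numeric vector.
#' @return one-row data.frame: `median`, `q1`, `q3`, `min`, `max`, `n`.
#' @export
box_summary <- function(values) {
  values <- as.numeric(values)
  values <- values[!is.na(values)]
  if (length(values) == 0) stop("`values` must be nonempty", call. = FALSE)
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  data.frame(median = q[2], q1 = q[1], q3 = q[3],
             min = min(values), max = max(values), n = length(values))
}

#' Chi-square comparison of two proportions
#'
#' 2x2 chi-square test for equality of two proportions (e.g. fractions of
#' positive cells between conditions). No continuity correction by
#' default; set `correct = TRUE` for the Yates-corrected statistic.
#'
#' @param pos_a,n_a positives and total in group A.
#' @param pos_b,n_b positives and total in group B.
#' @param correct apply Yates continuity correction (default FALSE).
#' @return list with `statistic`, `p_value`, `df` (= 1).
#' @export
compare_proportions <- function(pos_a, n_a, pos_b, n_b, correct = FALSE) {
  if (pos_a < 0 || pos_b < 0 || pos_a > n_a || pos_b > n_b) {
    stop("need 0 <= pos <= n in each group", call. = FALSE)
  }
  tab <- matrix(c(pos_a, n_a - pos_a, pos_b, n_b - pos_b),
                nrow = 2, byrow = TRUE)
  if (pos_a + pos_b == 0 || pos_a + pos_b == n_a + n_b) {
    # degenerate margin: no variation in outcome, nothing to test
    return(list(statistic = 0, p_value = 1, df = 1L))
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  list(statistic = unname(ct$statistic), p_value = ct$p.value, df = 1L)
}
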