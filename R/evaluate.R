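# Cohort statistics: group-by-parity tables, relative risks with Katz
# confidence intervals, chi-square tests of independence, and the
# notch-style median confidence interval used to compare replicated
# decision systems.

#' Group-by-parity counts of the reference delivery cohort
#'
#' Parity distribution of the 40,976-birth reference population with
#' blood-gas-confirmed outcomes that this package's methods target:
#' healthy 21,691 / 15,855, acidosis 1,971 / 1,085 and HIE 250 / 124
#' (nulliparous / multiparous). Shipped as the packaged fixture for the
#' relative-risk computations.
#'
#' @return Tibble `group`, `nulliparous`, `multiparous`.
#' @export
hie_cohort_counts <- function() {
  tibble(
    group = group_levels,
    nulliparous = c(21691, 1971, 250),
    multiparous = c(15855, 1085, 124)
  )
}

#' Tabulate a cohort by outcome group and parity
#'
#' @param births Tibble with `group` and `parity` columns.
#' @return Tibble `group`, `nulliparous`, `multiparous` (counts; all
#'   groups listed, zero when empty).
#' @export
build_table <- function(births) {
  out <- tibble(
    group = group_levels,
    nulliparous = 0L,
    multiparous = 0L
  )
  if (nrow(births) == 0L) {
    return(out)
  }
  tab <- table(
    factor(births$group, levels = group_levels),
    factor(births$parity, levels = parity_levels)
  )
  out$nulliparous <- as.integer(tab[, "nulliparous"])
  out$multiparous <- as.integer(tab[, "multiparous"])
  out
}

#' Chi-square test of independence for a 2x2 table
#'
#' Pearson statistic on 1 degree of freedom, without continuity
#' correction.
#'
#' @param tab 2x2 numeric matrix of counts.
#' @return Tibble `statistic`, `df`, `p_value`.
#' @export
chi_square_independence <- function(tab) {
  tab <- as.matrix(tab)
  if (!identical(dim(tab), c(2L, 2L))) stop_input("`tab` must be 2x2")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop_input("degenerate margins: every row and column needs a positive total")
  }
  ct <- chisq.test(tab, correct = FALSE)
  tibble(
    statistic = unname(ct$statistic),
    df = unname(ct$parameter),
    p_value = ct$p.value
  )
}

#' Relative risk of an adverse outcome under nulliparity
#'
#' Risk ratio of the outcome for nulliparous versus multiparous births,
#' with denominators all births of each parity. `outcome = "hie"` counts
#' HIE cases only; `outcome = "acidosis"` uses the acidosis criterion,
#' which HIE cases also meet (HIE is defined as acidosis plus
#' encephalopathy), so both the acidosis and HIE rows are cases. The 95%
#' confidence interval uses the Katz log method,
#' `exp(log RR +/- 1.96 * sqrt(1/a - 1/N1 + 1/c - 1/N0))`, and the p-value
#' is the 2x2 chi-square test of independence.
#'
#' @param counts Group-by-parity counts as from [build_table()] or
#'   [hie_cohort_counts()].
#' @param outcome `"hie"` or `"acidosis"`.
#' @param conf_level Confidence level of the interval.
#' @return One-row tibble: `outcome`, `cases_nulliparous`,
#'   `n_nulliparous`, `cases_multiparous`, `n_multiparous`, `rr`,
#'   `ci_low`, `ci_high`, `statistic`, `p_value`.
#' @export
relative_risk <- function(counts, outcome = c("hie", "acidosis"), conf_level = 0.95) {
  outcome <- match.arg(outcome)
  case_groups <- if (outcome == "hie") "hie" else c("acidosis", "hie")
  is_case <- counts$group %in% case_groups
  a <- sum(counts$nulliparous[is_case])
  n1 <- sum(counts$nulliparous)
  cc <- sum(counts$multiparous[is_case])
  n0 <- sum(counts$multiparous)
  rr <- (a / n1) / (cc / n0)
  if (a == 0 || cc == 0) {
    warn("zero case cell: the Katz confidence interval is undefined")
    ci <- c(NA_real_, NA_real_)
  } else {
    z <- -qnorm((1 - conf_level) / 2)
    se <- sqrt(1 / a - 1 / n1 + 1 / cc - 1 / n0)
    ci <- exp(log(rr) + c(-1, 1) * z * se)
  }
  chi <- chi_square_independence(matrix(c(a, n1 - a, cc, n0 - cc), 2, byrow = TRUE))
  tibble(
    outcome = outcome,
    cases_nulliparous = a, n_nulliparous = n1,
    cases_multiparous = cc, n_multiparous = n0,
    rr = rr, ci_low = ci[1], ci_high = ci[2],
    statistic = chi$statistic, p_value = chi$p_value
  )
}

#' Notch-style confidence interval of the median
#'
#' `median(x) +/- 1.57 * IQR(x) / sqrt(n)`, the classic notched-boxplot
#' interval, with quartiles by the linear-interpolation convention
#' (`stats::quantile` type 7).
#'
#' @param x Numeric sample, length at least 2.
#' @return Tibble `median`, `ci_low`, `ci_high`, `n`.
#' @export
median_ci <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 2) stop_input("`median_ci()` needs at least 2 observations")
  m <- median(x)
  half <- 1.57 * unname(diff(quantile(x, c(0.25, 0.75), type = 7))) / sqrt(n)
  tibble(median = m, ci_low = m - half, ci_high = m + half, n = n)
}

#' Two-sided Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Exact null distribution when both samples have fewer than 20
#' observations and there are no ties; otherwise the normal approximation
#' with tie correction (no continuity correction). Samples that are
#' completely tied across both arms carry no ordering information and
#' return p = 1.
#'
#' @param x,y Numeric samples.
#' @param exact_below Use the exact branch when both sample sizes are below
#'   this and there are no ties.
#' @return Tibble `statistic` (the Mann-Whitney U of `x`), `p_value`,
#'   `method` (`"exact"` or `"normal"`).
#' @export
rank_sum_test <- function(x, y, exact_below = 20) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  if (length(x) == 0 || length(y) == 0) stop_input("both samples must be non-empty")
  if (length(unique(c(x, y))) == 1L) {
    return(tibble(
      statistic = length(x) * length(y) / 2,
      p_value = 1, method = "degenerate"
    ))
  }
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- !ties && length(x) < exact_below && length(y) < exact_below
  wt <- suppressWarnings(
    wilcox.test(x, y, alternative = "two.sided", exact = exact, correct = FALSE)
  )
  tibble(
    statistic = unname(wt$statistic),
    p_value = min(1, wt$p.value),
    method = if (exact) "exact" else "normal"
  )
}
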