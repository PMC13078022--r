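# Group-comparison statistics used throughout the similarity framework.
# All tests are two-sided and delegate to the standard base-R routines;
# routing (two groups vs more, 2x2 vs larger tables) follows the
# conventions of clinicopathological comparison tables.

new_group_comparison <- function(feature, test, statistic, p_value,
                                 group_summaries, method) {
  structure(
    list(feature = feature, test = test, statistic = statistic,
      p_value = p_value, group_summaries = group_summaries, method = method),
    class = "mf_group_comparison"
  )
}

#' Compare a numeric feature between groups
#'
#' Two groups are compared with a two-sided Mann-Whitney U (Wilcoxon
#' rank-sum) test -- exact when the combined sample size is at most 10 and
#' tie-free, otherwise the tie-corrected normal approximation -- and three or
#' more groups with a Kruskal-Wallis test.
#'
#' @param data A data frame.
#' @param value,group Column names (strings) of the numeric feature and the
#'   grouping variable.
#' @param test `"auto"` (route on the number of groups), `"mann_whitney"` or
#'   `"kruskal_wallis"`.
#' @return An `mf_group_comparison`; see [tidy.mf_group_comparison()] and
#'   [glance.mf_group_comparison()].
#' @export
compare_numeric_groups <- function(data, value, group, test = "auto") {
  test <- match.arg(test, c("auto", "mann_whitney", "kruskal_wallis"))
  vals <- data[[value]]
  grp <- as.character(data[[group]])
  keep <- !is.na(vals) & !is.na(grp)
  vals <- vals[keep]
  grp <- grp[keep]
  groups <- split(vals, grp)
  if (length(groups) < 2) abort("need at least two groups")
  if (any(lengths(groups) == 0)) abort("every group needs at least one value")
  if (test == "auto") {
    test <- if (length(groups) == 2) "mann_whitney" else "kruskal_wallis"
  }
  if (test == "mann_whitney") {
    if (length(groups) != 2) abort("Mann-Whitney requires exactly two groups")
    n_tot <- length(vals)
    exact <- n_tot <= 10 && !anyDuplicated(vals)
    ht <- suppressWarnings(wilcox.test(groups[[1]], groups[[2]],
      exact = exact, correct = FALSE))
    stat <- unname(ht$statistic)
  } else {
    ht <- kruskal.test(vals, factor(grp))
    stat <- unname(ht$statistic)
  }
  summaries <- tibble(
    group = names(groups),
    n = lengths(groups),
    median = purrr::map_dbl(groups, median)
  )
  new_group_comparison(value, test, stat, unname(ht$p.value), summaries,
    ht$method)
}

#' Compare categorical counts between groups
#'
#' A 2x2 contingency table is tested with Fisher's exact test (two-sided,
#' probability-mass rule); larger tables with a chi-squared test without
#' continuity correction.
#'
#' @param table A contingency table or matrix of non-negative integer counts.
#' @param test `"auto"` (Fisher for 2x2, chi-squared otherwise), `"fisher"`
#'   or `"chi_squared"`.
#' @return An `mf_group_comparison`.
#' @export
compare_categorical_groups <- function(table, test = "auto") {
  test <- match.arg(test, c("auto", "fisher", "chi_squared"))
  tab <- as.matrix(table)
  if (any(tab < 0) || any(tab != round(tab))) {
    abort("contingency counts must be non-negative integers")
  }
  if (test == "auto") {
    test <- if (all(dim(tab) == c(2, 2))) "fisher" else "chi_squared"
  }
  if (test == "fisher") {
    if (!all(dim(tab) == c(2, 2))) {
      abort("Fisher's exact test is routed to 2x2 tables; use chi_squared")
    }
    ht <- fisher.test(tab)
    stat <- unname(ht$estimate)
  } else {
    ht <- suppressWarnings(chisq.test(tab, correct = FALSE))
    stat <- unname(ht$statistic)
  }
  summaries <- as_tibble(as.data.frame(as.table(tab), stringsAsFactors = FALSE))
  names(summaries) <- c("row", "col", "n")[seq_len(ncol(summaries))]
  new_group_comparison("counts", test, stat, unname(ht$p.value), summaries,
    ht$method)
}

#' @export
print.mf_group_comparison <- function(x, ...) {
  cat("<mf_group_comparison> ", x$method, "\n", sep = "")
  cat(sprintf("  feature: %s   statistic = %.4g   p = %.4g\n",
    x$feature, x$statistic, x$p_value))
  invisible(x)
}

#' Tidy a group comparison
#'
#' @param x An `mf_group_comparison`.
#' @param ... Unused.
#' @return Per-group summaries (n and median, or cell counts) as a tibble.
#' @export
tidy.mf_group_comparison <- function(x, ...) {
  x$group_summaries
}

#' One-row summary of a group comparison
#'
#' @param x An `mf_group_comparison`.
#' @param ... Unused.
#' @return A one-row tibble: `feature`, `test`, `statistic`, `p.value`,
#'   `method`.
#' @export
glance.mf_group_comparison <- function(x, ...) {
  tibble(feature = x$feature, test = x$test, statistic = x$statistic,
    p.value = x$p_value, method = x$method)
}

#' Optional Benjamini-Hochberg adjustment for a table of p-values
#'
#' The primary analyses use unadjusted two-sided p-values with the
#' conventional 0.05 level; this helper adds an FDR column for exploratory
#' tables with many features.
#'
#' @param df Data frame with a `p.value` column.
#' @return `df` with an added `p.adjust` column (BH).
#' @export
adjust_pvalues <- function(df) {
  stopifnot("p.value" %in% names(df))
  mutate(df, p.adjust = p.adjust(.data$p.value, method = "BH"))
}
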