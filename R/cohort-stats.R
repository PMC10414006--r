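# Descriptive tables and group comparisons following standard clinical
# reporting conventions: mean (SD) for normally distributed continuous variables,
# median (IQR) for ordinal or non-normal variables, n (%) for binaries;
# t / Mann-Whitney / ANOVA / Kruskal-Wallis for means and medians,
# chi-square or Fisher for categories, Spearman for ordinal-ordinal.

variable_kind <- function(x) {
  x <- x[!is.na(x)]
  if (is.logical(x) || length(unique(x)) <= 2L) return("binary")
  if (is.ordered(x)) return("ordinal")
  if (is.numeric(x)) {
    vals <- unique(x)
    if (all(vals == round(vals)) && length(vals) <= 8L) return("ordinal")
    return("continuous")
  }
  if (is.factor(x) || is.character(x)) return("categorical")
  "continuous"
}

is_normalish <- function(x, alpha = 0.05) {
  x <- x[!is.na(x)]
  if (length(unique(x)) < 4L || length(x) < 4L) return(FALSE)
  if (length(x) > 4999L) x <- x[seq(1L, length(x), length.out = 4999L)]
  stats::shapiro.test(x)$p.value >= alpha
}

fmt_mean_sd <- function(x) sprintf("%.1f (%.1f)", mean(x, na.rm = TRUE),
                                   stats::sd(x, na.rm = TRUE))
fmt_median_iqr <- function(x) {
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), na.rm = TRUE, type = 2)
  fmt <- function(v) trimws(formatC(v, format = "fg", digits = 3))
  sprintf("%s (%s-%s)", fmt(q[2L]), fmt(q[1L]), fmt(q[3L]))
}
fmt_n_pct <- function(x) {
  x <- x[!is.na(x)]
  n_pos <- sum(as.logical(x))
  sprintf("%d (%.1f)", n_pos, 100 * n_pos / length(x))
}

#' Descriptive cohort table
#'
#' One row per variable per group, with the summary convention chosen from
#' the variable kind: `n (%)` for binary variables, `median (IQR)` for
#' ordinal or non-normal continuous variables (normality triaged by a
#' Shapiro-Wilk check at alpha = 0.05), `mean (SD)` otherwise. Percentages
#' are `100 * n / N` rounded to one decimal. When the grouping has exactly
#' two levels a comparison p-value per variable (see [compare_groups()]) is
#' appended.
#'
#' @param records A data frame of per-patient records.
#' @param variables Character vector of columns to summarise.
#' @param grouping Optional grouping column name (e.g. SVD type).
#' @return A tibble: `variable`, `kind`, one summary column per group (plus
#'   whole-cohort), and `p_value`/`test` when a two-level grouping is given.
#' @export
#' @examples
#' df <- tibble::tibble(g = rep(c("a", "b"), each = 10),
#'                      age = c(rnorm(10, 60), rnorm(10, 50)),
#'                      female = rep(c(TRUE, FALSE), 10))
#' cohort_table(df, c("age", "female"), grouping = "g")
cohort_table <- function(records, variables, grouping = NULL) {
  stopifnot(is.data.frame(records))
  records <- tibble::as_tibble(records)
  groups <- if (is.null(grouping)) list(all = records) else {
    gv <- records[[grouping]]
    if (anyNA(gv)) stop("grouping variable contains missing values", call. = FALSE)
    split(records, gv)
  }
  if (length(groups) == 0L ||
      any(vapply(groups, nrow, integer(1)) == 0L)) {
    stop("every group needs at least one record", call. = FALSE)
  }
  summarise_one <- function(x, kind) {
    x <- x[!is.na(x)]
    if (length(x) == 0L) return(NA_character_)
    switch(kind,
           binary = fmt_n_pct(x),
           ordinal = fmt_median_iqr(as.numeric(x)),
           continuous = if (is_normalish(x)) fmt_mean_sd(x) else fmt_median_iqr(x),
           categorical = paste(names(sort(table(x), decreasing = TRUE)),
                               collapse = "/"))
  }
  rows <- purrr::map_dfr(variables, function(v) {
    kind <- variable_kind(records[[v]])
    row <- tibble::tibble(variable = v, kind = kind,
                          overall = summarise_one(records[[v]], kind))
    for (gname in names(groups)) {
      row[[gname]] <- summarise_one(groups[[gname]][[v]], kind)
    }
    row
  })
  if (!is.null(grouping) && length(groups) == 2L) {
    cmp <- purrr::map_dfr(variables, function(v) {
      res <- compare_groups(records, v, grouping)
      tibble::tibble(variable = v, test = res$test, p_value = res$p_value)
    })
    rows <- dplyr::left_join(rows, cmp, by = "variable")
  }
  rows
}

#' Compare a variable between groups
#'
#' Test selection follows the variable kind: binary variables get Pearson's
#' chi-square, or Fisher's exact test when any expected cell count is below
#' 5; ordinal variables get Mann-Whitney U (2 groups) or Kruskal-Wallis;
#' continuous variables get Student t / ANOVA when both (all) groups pass a
#' Shapiro-Wilk normality check, Mann-Whitney / Kruskal-Wallis otherwise. If
#' both the variable and the grouping are ordinal, a Spearman correlation is
#' used. Degenerate (constant) variables return a not-applicable marker.
#'
#' @param records A data frame.
#' @param variable Column to test.
#' @param grouping Grouping column.
#' @return One-row tibble: `variable`, `test`, `statistic`, `p_value`
#'   (`test = "not applicable"` and `NA` p for degenerate input).
#' @export
compare_groups <- function(records, variable, grouping) {
  x <- records[[variable]]
  g <- records[[grouping]]
  keep <- !is.na(x) & !is.na(g)
  x <- x[keep]; g <- g[keep]
  na_row <- function() tibble::tibble(variable = variable,
                                      test = "not applicable",
                                      statistic = NA_real_, p_value = NA_real_)
  if (length(unique(x)) < 2L || length(unique(g)) < 2L) return(na_row())
  kind_x <- variable_kind(x)
  kind_g <- variable_kind(g)
  out <- function(test, statistic, p) {
    tibble::tibble(variable = variable, test = test,
                   statistic = as.numeric(statistic), p_value = p)
  }

  if (kind_x == "ordinal" && kind_g == "ordinal") {
    ct <- suppressWarnings(
      stats::cor.test(as.numeric(x), as.numeric(g), method = "spearman"))
    return(out("spearman", ct$estimate, ct$p.value))
  }
  gf <- factor(g)
  if (kind_x %in% c("binary", "categorical")) {
    tab <- table(x, gf)
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(expected < 5)) {
      ft <- stats::fisher.test(tab)
      return(out("fisher", NA_real_, ft$p.value))
    }
    cs <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    return(out("chi-square", cs$statistic, cs$p.value))
  }
  xs <- split(as.numeric(x), gf)
  if (any(vapply(xs, function(v) length(unique(v)), integer(1)) < 2L)) {
    # a constant arm: rank tests still apply, mean tests do not
    kind_x <- "ordinal"
  }
  normal <- kind_x == "continuous" && all(vapply(xs, is_normalish, logical(1)))
  if (length(xs) == 2L) {
    if (normal) {
      tt <- stats::t.test(xs[[1L]], xs[[2L]])
      return(out("t", tt$statistic, tt$p.value))
    }
    wt <- suppressWarnings(stats::wilcox.test(xs[[1L]], xs[[2L]]))
    return(out("mann-whitney", wt$statistic, wt$p.value))
  }
  if (normal) {
    av <- stats::oneway.test(as.numeric(x) ~ gf, var.equal = TRUE)
    return(out("anova", av$statistic, av$p.value))
  }
  kw <- stats::kruskal.test(as.numeric(x), gf)
  out("kruskal-wallis", kw$statistic, kw$p.value)
}

#' Univariable screen at p < alpha
#'
#' Keeps variables whose univariable p-value is strictly below `alpha`
#' (default 0.1), then adds the always-included vascular function measures
#' (PS, vP, CVR columns) regardless of their p-values.
#'
#' @param results A tibble with `variable` and `p_value` columns (e.g. from
#'   [compare_groups()] rows).
#' @param alpha Screening level (default 0.1, strict inequality).
#' @param always_include Variables forced into the candidate list.
#' @return Character vector of candidate covariates.
#' @export
univariable_screen <- function(results, alpha = 0.1,
                               always_include = character()) {
  stopifnot(all(c("variable", "p_value") %in% names(results)))
  hits <- results$variable[!is.na(results$p_value) & results$p_value < alpha]
  union(hits, always_include)
}
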