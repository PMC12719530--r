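#' Glucose-tolerance-test area under the curve
#'
#' Trapezoidal integration of the glucose-versus-time curve,
#' `sum(0.5 * (g_k + g_{k+1}) * (t_{k+1} - t_k))`, in min*mg/dL.
#'
#' @param data Data frame with the time and glucose columns, or `NULL` when
#'   vectors are given directly.
#' @param times Column name (tidy-selected) or numeric vector of times
#'   (min), strictly increasing.
#' @param glucose Column name or numeric vector of glucose values (mg/dL),
#'   non-negative.
#' @return The AUC (min*mg/dL).
#' @examples
#' gtt_auc(times = c(0, 10, 30, 60, 90, 120),
#'         glucose = c(120, 350, 420, 380, 300, 250))
#' @export
gtt_auc <- function(data = NULL, times, glucose) {
  if (!is.null(data)) {
    times <- rlang::eval_tidy(rlang::enquo(times), data)
    glucose <- rlang::eval_tidy(rlang::enquo(glucose), data)
  }
  if (length(times) < 2) stop("need at least 2 time points", call. = FALSE)
  if (length(times) != length(glucose))
    stop("times and glucose must have equal length", call. = FALSE)
  if (is.unsorted(times, strictly = TRUE))
    stop("times must be strictly increasing", call. = FALSE)
  if (any(glucose < 0)) stop("glucose must be non-negative", call. = FALSE)
  sum(0.5 * (glucose[-length(glucose)] + glucose[-1]) * diff(times))
}

#' Select the between-group test
#'
#' The study's normality-gated policy: any group with n <= 10 triggers
#' non-parametric analysis (Mann-Whitney U for two groups, Kruskal-Wallis
#' for more); for larger groups, Shapiro-Wilk normality is checked per group
#' at alpha = 0.05 and the two-tailed Student's t-test (two groups) or ANOVA
#' (more) is used only when every group passes, otherwise the
#' non-parametric branch applies.
#'
#' @param values List of numeric vectors, one per group (or a single vector
#'   with `groups`).
#' @param groups Optional grouping factor when `values` is one vector.
#' @param alpha_normality Shapiro-Wilk significance level; default 0.05.
#' @return A list: `test` (one of `"mann-whitney"`, `"kruskal-wallis"`,
#'   `"t-test"`, `"anova"`), `n` (group sizes), `normal` (per-group
#'   Shapiro-Wilk pass flags, `NA` when not evaluated).
#' @examples
#' select_test(list(rnorm(8), rnorm(8)))$test      # "mann-whitney"
#' @export
select_test <- function(values, groups = NULL, alpha_normality = 0.05) {
  if (!is.list(values)) values <- split(values, groups)
  if (length(values) < 2) stop("need at least 2 groups", call. = FALSE)
  n <- vapply(values, length, integer(1))
  k <- length(values)
  if (any(n <= 10)) {
    return(list(test = if (k == 2) "mann-whitney" else "kruskal-wallis",
                n = n, normal = rep(NA, k)))
  }
  normal <- vapply(values, function(v) {
    stats::shapiro.test(v)$p.value >= alpha_normality
  }, logical(1))
  if (all(normal)) {
    list(test = if (k == 2) "t-test" else "anova", n = n, normal = normal)
  } else {
    list(test = if (k == 2) "mann-whitney" else "kruskal-wallis",
         n = n, normal = normal)
  }
}

#' Compare groups with the policy-selected test
#'
#' Applies [select_test()] and runs the chosen classical test. Summaries
#' follow the reporting convention: mean +/- SD for the parametric branch,
#' median \[IQR\] for the non-parametric branch.
#'
#' @param data Data frame in long format.
#' @param value,group Column names (tidy-selected) of the measurement and
#'   group label.
#' @param alpha Significance threshold (two-sided); default 0.05.
#' @return A one-row tibble: `test`, `statistic`, `p_value`, `significant`,
#'   `n1`, `n2`, ... and per-group `summary` strings.
#' @export
compare_groups <- function(data, value, group, alpha = 0.05) {
  v <- rlang::eval_tidy(rlang::enquo(value), data)
  g <- factor(rlang::eval_tidy(rlang::enquo(group), data))
  keep <- is.finite(v) & !is.na(g)
  v <- v[keep]; g <- droplevels(g[keep])
  vals <- split(v, g)
  sel <- select_test(vals)
  res <- switch(sel$test,
    "mann-whitney" = stats::wilcox.test(vals[[1]], vals[[2]], exact = FALSE),
    "t-test" = stats::t.test(vals[[1]], vals[[2]], var.equal = FALSE),
    "kruskal-wallis" = stats::kruskal.test(v, g),
    "anova" = {
      a <- stats::aov(v ~ g)
      s <- summary(a)[[1]]
      list(statistic = s[["F value"]][1], p.value = s[["Pr(>F)"]][1])
    })
  parametric <- sel$test %in% c("t-test", "anova")
  summaries <- vapply(vals, function(x) {
    if (parametric) sprintf("%.3g ± %.3g", mean(x), stats::sd(x))
    else sprintf("%.3g [%.3g-%.3g]", stats::median(x),
                 stats::quantile(x, 0.25), stats::quantile(x, 0.75))
  }, character(1))
  out <- tibble::tibble(
    test = sel$test,
    statistic = unname(res$statistic[1]),
    p_value = res$p.value,
    significant = res$p.value < alpha
  )
  for (i in seq_along(vals)) {
    out[[paste0("n_", names(vals)[i])]] <- length(vals[[i]])
    out[[paste0("summary_", names(vals)[i])]] <- summaries[i]
  }
  out
}

#' Spearman rank correlation
#'
#' Rank correlation between two paired measurements with its standard
#' p-value, as used to relate glucose tolerance to cardiovascular function
#' metrics.
#'
#' @param data Optional data frame; `x` and `y` are tidy-selected columns
#'   when given.
#' @param x,y Paired numeric vectors (or column names), n >= 4 after
#'   removing incomplete pairs.
#' @return A one-row tibble: `rho`, `p_value`, `n`.
#' @examples
#' correlate(x = 1:10, y = (1:10)^2)  # rho = 1
#' @export
correlate <- function(data = NULL, x, y) {
  if (!is.null(data)) {
    x <- rlang::eval_tidy(rlang::enquo(x), data)
    y <- rlang::eval_tidy(rlang::enquo(y), data)
  }
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 4) stop("need at least 4 complete pairs", call. = FALSE)
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  tibble::tibble(rho = unname(ct$estimate), p_value = ct$p.value,
                 n = length(x))
}
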