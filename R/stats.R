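#' Independent two-sample Student's t-test
#'
#' Pooled-variance Student's t (Welch available via `var_equal = FALSE`),
#' two-sided p from the t distribution on `n1 + n2 - 2` degrees of freedom.
#' Per-group 95% confidence intervals use each group's own standard error and
#' t critical value. Cohen's d uses the pooled SD. Zero pooled variance with
#' equal means is the identity case (`t = 0, p = 1`); with unequal means it
#' is degenerate and errors.
#'
#' @param group_1,group_2 Numeric vectors, at least 2 finite values each.
#' @param var_equal Pool the variances (default `TRUE`).
#' @param conf_level Confidence level for the per-group CIs (default 0.95).
#' @return An object of class `ttest_result`: a list with `t_statistic`,
#'   `df`, `p_value`, `mean_1`, `mean_2`, `ci95_1`, `ci95_2`, `n1`, `n2`,
#'   `pooled_sd`, `cohens_d`, `method`. Has [tidy()] and [glance()] methods.
#' @examples
#' t_test_independent(c(5.1, 4.9, 5.0, 5.2), c(5.6, 5.8, 5.5, 5.7))
#' @export
t_test_independent <- function(group_1, group_2, var_equal = TRUE,
                               conf_level = 0.95) {
  g1 <- group_1[is.finite(group_1)]
  g2 <- group_2[is.finite(group_2)]
  n1 <- length(g1)
  n2 <- length(g2)
  if (n1 < 2 || n2 < 2) abort("Each group needs at least 2 finite values.")
  m1 <- mean(g1)
  m2 <- mean(g2)
  v1 <- stats::var(g1)
  v2 <- stats::var(g2)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  if (var_equal) {
    if (sp2 == 0) {
      if (m1 != m2) {
        abort("Degenerate test: zero pooled variance with unequal means.")
      }
      tstat <- 0
      df <- n1 + n2 - 2
    } else {
      tstat <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
      df <- n1 + n2 - 2
    }
  } else {
    se2 <- v1 / n1 + v2 / n2
    if (se2 == 0) {
      if (m1 != m2) abort("Degenerate test: zero variance with unequal means.")
      tstat <- 0
      df <- n1 + n2 - 2
    } else {
      tstat <- (m1 - m2) / sqrt(se2)
      df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    }
  }
  p <- 2 * pt(-abs(tstat), df)
  ci <- function(m, v, n) {
    crit <- qt(1 - (1 - conf_level) / 2, n - 1)
    m + c(-1, 1) * crit * sqrt(v / n)
  }
  out <- list(
    t_statistic = tstat, df = df, p_value = p,
    mean_1 = m1, mean_2 = m2,
    ci95_1 = ci(m1, v1, n1), ci95_2 = ci(m2, v2, n2),
    n1 = n1, n2 = n2,
    pooled_sd = sqrt(sp2),
    cohens_d = if (sp2 > 0) (m1 - m2) / sqrt(sp2) else 0,
    method = if (var_equal) "student" else "welch"
  )
  structure(out, class = "ttest_result")
}

#' @export
print.ttest_result <- function(x, ...) {
  cat(sprintf(
    "Two-sample %s t-test\n  t = %.4g, df = %.4g, p = %.4g\n  mean 1 = %.4g [%.4g, %.4g] (n = %d)\n  mean 2 = %.4g [%.4g, %.4g] (n = %d)\n  Cohen's d = %.3g\n",
    if (x$method == "student") "Student's" else "Welch's",
    x$t_statistic, x$df, x$p_value,
    x$mean_1, x$ci95_1[1], x$ci95_1[2], x$n1,
    x$mean_2, x$ci95_2[1], x$ci95_2[2], x$n2,
    x$cohens_d
  ))
  invisible(x)
}

#' @method tidy ttest_result
#' @export
tidy.ttest_result <- function(x, ...) {
  tibble::tibble(
    estimate = x$mean_1 - x$mean_2,
    mean_1 = x$mean_1, mean_2 = x$mean_2,
    ci_low_1 = x$ci95_1[1], ci_high_1 = x$ci95_1[2],
    ci_low_2 = x$ci95_2[1], ci_high_2 = x$ci95_2[2],
    statistic = x$t_statistic, df = x$df, p.value = x$p_value,
    cohens_d = x$cohens_d, n1 = x$n1, n2 = x$n2, method = x$method
  )
}

#' @method glance ttest_result
#' @export
glance.ttest_result <- function(x, ...) {
  tibble::tibble(
    statistic = x$t_statistic, df = x$df,
    p.value = x$p_value, cohens_d = x$cohens_d
  )
}

#' Pearson correlation with two-sided p
#'
#' Product-moment correlation; p-value from
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom
#' (Spearman available via `method`). Pairs with missing values are dropped.
#' Constant input makes the correlation undefined: the result carries
#' `r = NA` and a QC note rather than an error.
#'
#' @param x,y Numeric vectors of equal length (n >= 3 after removing
#'   incomplete pairs).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return An object of class `correlation_result`: list with `r`, `n`,
#'   `p_value`, `method`, `note`. Has a [tidy()] method.
#' @examples
#' pearson_correlation(1:10, (1:10) * 2 + 1)
#' @export
pearson_correlation <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  ok <- complete.cases(x, y)
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  if (n < 3) abort("Correlation needs at least 3 complete pairs.")
  if (sd(x) == 0 || sd(y) == 0) {
    out <- list(
      r = NA_real_, n = n, p_value = NA_real_, method = method,
      note = "undefined: constant input"
    )
    return(structure(out, class = "correlation_result"))
  }
  ct <- stats::cor.test(x, y, method = method, exact = FALSE)
  out <- list(
    r = unname(ct$estimate), n = n, p_value = ct$p.value,
    method = method, note = NA_character_
  )
  structure(out, class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf(
    "%s correlation: r = %.4g, n = %d, p = %.4g%s\n",
    tools::toTitleCase(x$method), x$r, x$n, x$p_value,
    if (!is.na(x$note)) paste0(" (", x$note, ")") else ""
  ))
  invisible(x)
}

#' @method tidy correlation_result
#' @export
tidy.correlation_result <- function(x, ...) {
  tibble::tibble(
    estimate = x$r, n = x$n, p.value = x$p_value,
    method = x$method, note = x$note
  )
}

#' Post-hoc power of the two-sided two-sample t-test
#'
#' Power at effect size `d` (Cohen's d) with group sizes `n1`, `n2`, computed
#' from the noncentral t distribution with noncentrality
#' `d * sqrt(n1 * n2 / (n1 + n2))` and `n1 + n2 - 2` degrees of freedom.
#'
#' @param d Standardized effect size (Cohen's d).
#' @param n1,n2 Group sizes (each at least 2).
#' @param alpha Two-sided significance level in (0, 1), default 0.05.
#' @return An object of class `power_result`: list with `effect_size_d`,
#'   `n1`, `n2`, `alpha`, `power`.
#' @examples
#' posthoc_power_t(0.5, 19, 19)
#' @export
posthoc_power_t <- function(d, n1, n2, alpha = 0.05) {
  if (n1 < 2 || n2 < 2) abort("Each group needs n >= 2.")
  if (alpha <= 0 || alpha >= 1) abort("alpha must lie in (0, 1).")
  df <- n1 + n2 - 2
  ncp <- d * sqrt(n1 * n2 / (n1 + n2))
  crit <- qt(1 - alpha / 2, df)
  power <- pt(-crit, df, ncp = ncp) + pt(crit, df, ncp = ncp, lower.tail = FALSE)
  structure(
    list(effect_size_d = d, n1 = n1, n2 = n2, alpha = alpha, power = power),
    class = "power_result"
  )
}

#' @export
print.power_result <- function(x, ...) {
  cat(sprintf(
    "Two-sample t power: d = %.3g, n = %d + %d, alpha = %.3g -> power = %.3f\n",
    x$effect_size_d, x$n1, x$n2, x$alpha, x$power
  ))
  invisible(x)
}

#' @method tidy power_result
#' @export
tidy.power_result <- function(x, ...) {
  tibble::tibble(
    effect_size_d = x$effect_size_d, n1 = x$n1, n2 = x$n2,
    alpha = x$alpha, power = x$power
  )
}
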