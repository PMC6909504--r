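# Shared statistical primitives used by the 4C, ChIP, expression and FISH
# stages.  Distribution functions delegate to base R; the test suite checks
# them against quadrature and sort-based oracles.

#' Chi-square survival function
#'
#' Upper-tail probability of the chi-square distribution (the regularized
#' upper incomplete gamma function), used for G-test p-values (df = 1 for
#' a 2x2 table).
#'
#' @param x non-negative quantile(s).
#' @param df degrees of freedom (>= 1).
#' @return `P(X >= x)` for `X ~ chi-square(df)`.
#' @export
chisq_sf <- function(x, df) {
  if (any(x < 0)) stop("x must be >= 0")
  if (df < 1) stop("df must be >= 1")
  stats::pchisq(x, df = df, lower.tail = FALSE)
}

#' Linear-interpolation (type-7) quantile
#'
#' @param values non-empty numeric vector.
#' @param q probabilities in `[0, 1]`.
#' @export
quantile7 <- function(values, q) {
  if (length(values) == 0) stop("empty value vector")
  unname(stats::quantile(values, probs = q, type = 7, names = FALSE))
}

#' Interquartile range (type-7 quantiles)
#' @param values numeric vector.
#' @export
iqr7 <- function(values) quantile7(values, 0.75) - quantile7(values, 0.25)

#' Container for a test result
#'
#' @param statistic_name e.g. `"G"` or `"U"`.
#' @param statistic the observed statistic.
#' @param p_value two-sided p-value in `[0, 1]`.
#' @param df degrees of freedom, or NA for exact tests.
#' @param exact logical; was the p-value computed by exact enumeration.
#' @param n problem size (observations or table total).
#' @export
test_result <- function(statistic_name, statistic, p_value, df = NA,
                        exact = FALSE, n = NA) {
  if (!is.na(p_value) && (p_value < 0 || p_value > 1))
    stop("p-value outside [0, 1]")
  structure(list(statistic_name = statistic_name,
                 statistic = as.numeric(statistic),
                 p_value = as.numeric(p_value), df = df,
                 exact = isTRUE(exact), n = n),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s = %.6g, p = %.4g (%s%s)\n", x$statistic_name, x$statistic,
              x$p_value,
              if (x$exact) "exact" else paste0("df = ", x$df),
              if (is.na(x$n)) "" else paste0(", n = ", x$n)))
  invisible(x)
}
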