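#' Univariate screening tests
#'
#' The three univariate tests used to compare each candidate variable
#' between one case group and the control group: Pearson's chi-squared test
#' without continuity correction for categorical variables, Welch's
#' two-sample t test for approximately symmetric continuous variables, and
#' the tie-corrected normal approximation to the Mann-Whitney rank-sum test
#' for skewed laboratory values. Each returns a `test_result` with the
#' statistic, its degrees of freedom where applicable, and a two-sided
#' p-value.
#'
#' @name screening-tests
NULL

test_result <- function(statistic_name, statistic, p_value, df = NA_real_) {
  stopifnot(p_value >= 0, p_value <= 1)
  structure(list(statistic_name = statistic_name,
                 statistic = as.numeric(statistic),
                 df = as.numeric(df), p_value = as.numeric(p_value)),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("<test_result> %s = %.4f%s, p = %.4g\n", x$statistic_name,
              x$statistic,
              if (!is.na(x$df)) sprintf(" (df = %g)", x$df) else "",
              x$p_value))
  invisible(x)
}

#' @rdname screening-tests
#' @param table contingency table (matrix of nonnegative counts, at least
#'   2x2) with groups in rows and variable states in columns.
#' @return A `test_result` (`statistic_name` one of `"chi2"`, `"t"`, `"Z"`).
#' @export
pearson_chi2 <- function(table) {
  table <- as.matrix(table)
  if (nrow(table) < 2L || ncol(table) < 2L)
    stop("contingency table must be at least 2x2")
  if (any(table < 0)) stop("negative count")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("zero row/column margin: expected counts undefined")
  ht <- stats::chisq.test(table, correct = FALSE)
  test_result("chi2", ht$statistic, ht$p.value, df = ht$parameter)
}

#' @rdname screening-tests
#' @param a,b either numeric sample vectors or summary lists
#'   `list(mean =, sd =, n =)`; both arguments must be of the same form.
#' @export
welch_t <- function(a, b) {
  as_summ <- function(x) {
    if (is.list(x)) {
      stopifnot(!is.null(x$mean), !is.null(x$sd), !is.null(x$n))
      if (x$n < 2L) stop("summary n must be >= 2")
      if (x$sd < 0) stop("negative sd")
      x
    } else {
      x <- as.numeric(x)
      if (length(x) < 2L) stop("need at least 2 observations per sample")
      list(mean = mean(x), sd = stats::sd(x), n = length(x))
    }
  }
  if (!is.list(a) && !is.list(b)) {
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      if (mean(a) == mean(b)) {
        warning("both samples constant and equal: t undefined, returning 0")
        return(test_result("t", 0, 1, df = length(a) + length(b) - 2))
      }
    }
    ht <- stats::t.test(a, b, var.equal = FALSE)
    return(test_result("t", ht$statistic, ht$p.value, df = ht$parameter))
  }
  sa <- as_summ(a); sb <- as_summ(b)
  va <- sa$sd^2 / sa$n; vb <- sb$sd^2 / sb$n
  if (va + vb == 0) {
    warning("both sds zero: t undefined, returning 0")
    return(test_result("t", 0, 1, df = sa$n + sb$n - 2))
  }
  t <- (sa$mean - sb$mean) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (sa$n - 1) + vb^2 / (sb$n - 1))
  test_result("t", t, 2 * stats::pt(-abs(t), df), df = df)
}

#' @rdname screening-tests
#' @export
mann_whitney_z <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  n1 <- length(a); n2 <- length(b)
  if (n1 < 1L || n2 < 1L) stop("both samples must be non-empty")
  r <- rank(c(a, b))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2   # Mann-Whitney U for sample a
  n <- n1 + n2
  ties <- table(c(a, b))
  tie_term <- sum(ties^3 - ties)
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1)))
  if (sigma2 <= 0) {
    warning("all values tied across both samples: Z undefined, returning 0")
    return(test_result("Z", 0, 1))
  }
  z <- (u - n1 * n2 / 2) / sqrt(sigma2)
  test_result("Z", z, 2 * stats::pnorm(-abs(z)))
}

#' Screen candidate variables against the control group
#'
#' Compares every codebook variable between the named case group and the
#' control group: categorical variables by Pearson's chi-squared test on
#' the group-by-state contingency table, continuous variables by Welch's t
#' test, and variables listed in `nonparametric` by the rank-sum Z test.
#' Variables excluded for the outcome in the codebook (fasting blood
#' glucose for the diabetes analysis in the default codebook) are omitted
#' from the report entirely. Continuous statistics are oriented as control
#' minus case.
#'
#' No multiplicity adjustment is applied by default, matching the original
#' univariate screening; set `adjust` to a [stats::p.adjust()] method to
#' gate on adjusted p-values instead.
#'
#' @param cohort encoded cohort data.frame with a `group` column.
#' @param case_group case-group label present in `cohort$group`.
#' @param cb a [codebook()]; defaults to [default_codebook()].
#' @param alpha selection threshold on the (possibly adjusted) p-value.
#' @param nonparametric variables tested by rank-sum Z rather than t.
#' @param control_group label of the control group.
#' @param adjust `"none"` (default) or a [stats::p.adjust()] method.
#' @return A list of class `"screening_report"` with `table` (data.frame:
#'   variable, test, statistic, df, p_value, selected) and `selected`
#'   (character vector of variables with p below `alpha`).
#' @export
screen_variables <- function(cohort, case_group, cb = default_codebook(),
                             alpha = 0.05,
                             nonparametric = c("fbg", "tg"),
                             control_group = "control",
                             adjust = "none") {
  stopifnot(is.data.frame(cohort), "group" %in% names(cohort))
  groups <- unique(cohort$group)
  if (!case_group %in% groups) stop("unknown case group: ", case_group)
  if (!control_group %in% groups)
    stop("unknown control group: ", control_group)
  sub <- cohort[cohort$group %in% c(control_group, case_group), ]
  is_ctrl <- sub$group == control_group
  excl <- cb$exclusions[[case_group]] %||% character()
  vars <- intersect(names(cb$variables), names(sub))
  vars <- setdiff(vars, excl)
  rows <- lapply(vars, function(nm) {
    spec <- cb$variables[[nm]]
    x <- sub[[nm]]
    res <- if (spec$kind == "categorical") {
      tab <- table(factor(sub$group, levels = c(control_group, case_group)),
                   factor(x, levels = sort(spec$states)))
      tab <- tab[, colSums(tab) > 0, drop = FALSE]
      pearson_chi2(tab)
    } else if (nm %in% nonparametric) {
      mann_whitney_z(x[is_ctrl], x[!is_ctrl])
    } else {
      welch_t(x[is_ctrl], x[!is_ctrl])
    }
    data.frame(variable = nm, test = res$statistic_name,
               statistic = res$statistic, df = res$df,
               p_value = res$p_value, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  p_gate <- if (identical(adjust, "none")) tab$p_value
            else stats::p.adjust(tab$p_value, method = adjust)
  tab$selected <- p_gate < alpha
  structure(list(table = tab, selected = tab$variable[tab$selected],
                 case_group = case_group, alpha = alpha),
            class = "screening_report")
}

#' @export
print.screening_report <- function(x, ...) {
  cat(sprintf("<screening_report> case group %s, alpha = %g: %d of %d selected\n",
              x$case_group, x$alpha, length(x$selected), nrow(x$table)))
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}
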