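#' Build a regression design from an encoded cohort
#'
#' Restricts the cohort to the named case group plus controls, defines the
#' binary outcome (case = 1), and prepares predictors: continuous variables
#' stay on their raw scale (the selection stage is run before any
#' discretization); categorical variables become factors with the
#' codebook's reference (control) level first, so indicator coefficients
#' are log odds ratios against the reference level.
#'
#' @param cohort encoded cohort data.frame with a `group` column.
#' @param case_group case-group label.
#' @param variables predictor variable names (codebook variables).
#' @param cb a [codebook()].
#' @param control_group control-group label.
#' @return A list of class `"design_matrix"`: `y` (0/1 integer vector),
#'   `data` (data.frame of predictors), `variables`.
#' @export
design_matrix <- function(cohort, case_group, variables,
                          cb = default_codebook(),
                          control_group = "control") {
  stopifnot(is.data.frame(cohort), "group" %in% names(cohort))
  sub <- cohort[cohort$group %in% c(control_group, case_group), , drop = FALSE]
  if (!nrow(sub)) stop("no rows for groups ", control_group, "/", case_group)
  y <- as.integer(sub$group == case_group)
  if (all(y == 0L) || all(y == 1L))
    stop("need at least one event and one non-event")
  bad <- setdiff(variables, names(sub))
  if (length(bad)) stop("variable not in cohort: ", bad[1L])
  X <- sub[variables]
  for (nm in variables) {
    spec <- cb$variables[[nm]]
    if (!is.null(spec) && spec$kind == "categorical") {
      lev <- c(spec$reference, setdiff(sort(spec$states), spec$reference))
      X[[nm]] <- factor(X[[nm]], levels = lev)
      X[[nm]] <- droplevels(X[[nm]])
    } else {
      X[[nm]] <- as.numeric(X[[nm]])
    }
  }
  structure(list(y = y, data = X, variables = variables),
            class = "design_matrix")
}

#' Fit a binary logistic regression
#'
#' Maximum-likelihood fit by iteratively reweighted least squares
#' ([stats::glm()] with a binomial family, convergence tolerance 1e-10, at
#' most 50 iterations). The covariance matrix is the inverse observed
#' information. Complete or quasi-complete separation is flagged when a
#' coefficient exceeds 15 in absolute value or the fit fails to converge.
#'
#' @param design a [design_matrix()].
#' @return An object of class `"logistic_fit"`: `coefficients`, `se`,
#'   `wald` (per-coefficient Wald chi-squared), `p_value`, `vcov`,
#'   `loglik`, `converged`, `iterations`, `separation_flag`,
#'   `variables`, and the underlying `glm` object.
#' @export
fit_logistic <- function(design) {
  stopifnot(inherits(design, "design_matrix"))
  df <- design$data
  df$.y <- design$y
  fml <- if (length(design$variables))
    stats::reformulate(design$variables, response = ".y")
  else stats::as.formula(".y ~ 1")
  fit <- stats::glm(fml, family = stats::binomial(), data = df,
                    control = stats::glm.control(epsilon = 1e-10,
                                                 maxit = 50))
  if (any(is.na(stats::coef(fit)))) {
    alias <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient design: collinear column(s) ",
         paste(alias, collapse = ", "))
  }
  beta <- stats::coef(fit)
  V <- stats::vcov(fit)
  se <- sqrt(diag(V))
  wald <- (beta / se)^2
  sep <- !fit$converged | any(abs(beta) > 15)
  if (sep) {
    worst <- names(beta)[which.max(abs(beta))]
    warning("possible complete/quasi-complete separation (term '", worst,
            "'): estimates unreliable")
  }
  structure(list(coefficients = beta, se = se, wald = wald,
                 p_value = stats::pchisq(wald, df = 1, lower.tail = FALSE),
                 vcov = V, loglik = as.numeric(stats::logLik(fit)),
                 converged = fit$converged, iterations = fit$iter,
                 separation_flag = sep, variables = design$variables,
                 glm = fit),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("<logistic_fit> %d terms, logLik = %.3f, %s in %d iterations\n",
              length(x$coefficients), x$loglik,
              if (x$converged) "converged" else "NOT converged",
              x$iterations))
  print(data.frame(beta = x$coefficients, se = x$se, wald_chi2 = x$wald,
                   p = x$p_value), digits = 4)
  invisible(x)
}

#' Likelihood-ratio test between nested logistic fits
#'
#' @param full,reduced [fit_logistic()] results on the same rows, with the
#'   reduced model's variables a subset of the full model's.
#' @return A `test_result` with the LR chi-squared statistic, its degrees
#'   of freedom (coefficient-count difference) and upper-tail p-value.
#' @export
lr_test <- function(full, reduced) {
  stopifnot(inherits(full, "logistic_fit"), inherits(reduced, "logistic_fit"))
  if (!all(reduced$variables %in% full$variables))
    stop("models are not nested")
  if (length(reduced$glm$y) != length(full$glm$y))
    stop("models fit on different rows")
  df <- length(full$coefficients) - length(reduced$coefficients)
  if (df < 0) stop("models are not nested")
  chi2 <- max(0, 2 * (full$loglik - reduced$loglik))
  test_result("chi2", chi2,
              if (df == 0) 1 else stats::pchisq(chi2, df, lower.tail = FALSE),
              df = df)
}

#' Forward stepwise selection by likelihood ratio
#'
#' Forward:LR selection: at each step the candidate with the smallest
#' likelihood-ratio p-value below `p_enter` joins the model (all indicator
#' levels of a categorical variable enter as one block); after every entry,
#' any included variable whose removal LR p-value exceeds `p_remove` is
#' dropped (worst first). The procedure stops when no move is possible.
#' Ties are broken deterministically by candidate order, then name. An
#' intercept-only model is a legal result.
#'
#' @param cohort encoded cohort data.frame.
#' @param case_group case-group label.
#' @param candidates candidate variable names (typically the screened set).
#' @param cb a [codebook()].
#' @param p_enter entry threshold on the LR p-value (default 0.05).
#' @param p_remove removal threshold (default 0.10).
#' @param control_group control-group label.
#' @return A list of class `"stepwise_fit"`: `fit` (the final
#'   [fit_logistic()] result), `selected` (variables in entry order), and
#'   `trace` (data.frame: step, action, variable, lr_chi2, df, p_value).
#' @export
stepwise_forward_lr <- function(cohort, case_group, candidates,
                                cb = default_codebook(),
                                p_enter = 0.05, p_remove = 0.10,
                                control_group = "control") {
  candidates <- candidates[order(match(candidates, candidates))]  # stable
  fit_for <- function(vars) {
    fit_logistic(design_matrix(cohort, case_group, vars, cb,
                               control_group))
  }
  current <- character()
  cur_fit <- fit_for(current)
  trace <- list()
  step <- 0L
  seen <- character()
  repeat {
    step <- step + 1L
    pool <- setdiff(candidates, current)
    if (!length(pool)) break
    entry <- lapply(pool, function(v) {
      f <- suppressWarnings(fit_for(c(current, v)))
      tr <- lr_test(f, cur_fit)
      list(v = v, fit = f, chi2 = tr$statistic, df = tr$df, p = tr$p_value)
    })
    ps <- vapply(entry, `[[`, numeric(1), "p")
    nms <- vapply(entry, `[[`, character(1), "v")
    best <- order(ps, match(nms, candidates), nms)[1L]
    if (!(ps[best] < p_enter)) break
    e <- entry[[best]]
    current <- c(current, e$v)
    cur_fit <- e$fit
    trace[[length(trace) + 1L]] <-
      data.frame(step = step, action = "enter", variable = e$v,
                 lr_chi2 = e$chi2, df = e$df, p_value = e$p,
                 stringsAsFactors = FALSE)
    # backward sweep
    repeat {
      if (length(current) < 1L) break
      drop_p <- vapply(current, function(v) {
        red <- suppressWarnings(fit_for(setdiff(current, v)))
        lr_test(cur_fit, red)$p_value
      }, numeric(1))
      worst <- order(-drop_p, match(current, candidates), current)[1L]
      if (!(drop_p[worst] > p_remove)) break
      v <- current[worst]
      red <- suppressWarnings(fit_for(setdiff(current, v)))
      tr <- lr_test(cur_fit, red)
      current <- setdiff(current, v)
      cur_fit <- red
      trace[[length(trace) + 1L]] <-
        data.frame(step = step, action = "remove", variable = v,
                   lr_chi2 = tr$statistic, df = tr$df, p_value = tr$p_value,
                   stringsAsFactors = FALSE)
    }
    key <- paste(sort(current), collapse = "|")
    if (key %in% seen) break  # guard against enter/remove cycling
    seen <- c(seen, key)
  }
  structure(list(fit = cur_fit, selected = current,
                 trace = if (length(trace)) do.call(rbind, trace)
                         else data.frame(step = integer(), action = character(),
                                         variable = character(),
                                         lr_chi2 = numeric(), df = numeric(),
                                         p_value = numeric())),
            class = "stepwise_fit")
}

#' @export
print.stepwise_fit <- function(x, ...) {
  cat(sprintf("<stepwise_fit> %d variables selected: %s\n",
              length(x$selected), paste(x$selected, collapse = ", ")))
  invisible(x)
}

#' Odds ratios with confidence intervals
#'
#' Per non-intercept coefficient: OR = exp(beta) with the Wald interval
#' exp(beta +/- z * se) at the requested level (z = 1.959964 for 95%).
#'
#' @param fit a [fit_logistic()] result.
#' @param level confidence level (default 0.95).
#' @return data.frame: term, beta, se, wald_chi2, p_value, or, ci_lower,
#'   ci_upper.
#' @export
odds_ratios <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "logistic_fit"))
  z <- stats::qnorm(1 - (1 - level) / 2)
  keep <- names(fit$coefficients) != "(Intercept)"
  b <- fit$coefficients[keep]; s <- fit$se[keep]
  data.frame(term = names(b), beta = unname(b), se = unname(s),
             wald_chi2 = unname((b / s)^2),
             p_value = unname(fit$p_value[keep]),
             or = exp(unname(b)),
             ci_lower = exp(unname(b) - z * unname(s)),
             ci_upper = exp(unname(b) + z * unname(s)),
             stringsAsFactors = FALSE, row.names = NULL)
}
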