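# build a tiny encoded two-group cohort from per-cell counts
cohort_from_counts <- function(a, b, c, d) {
  # a: case & exposed, b: case & unexposed, c: control & exposed,
  # d: control & unexposed
  data.frame(
    group = c(rep("case", a + b), rep("control", c + d)),
    x = c(rep(1L, a), rep(0L, b), rep(1L, c), rep(0L, d)))
}

binary_cb <- codebook(list(variable_spec("x", "categorical",
                                         states = c(no = 0, yes = 1),
                                         reference = 0)))

test_that("logistic slope on a 2x2 table equals the closed-form log OR", {
  coh <- cohort_from_counts(a = 40, b = 20, c = 25, d = 55)
  fit <- fit_logistic(design_matrix(coh, "case", "x", binary_cb))
  # saturated 2x2 MLE: slope = ln(ad/bc), intercept = ln(b/d)
  expect_equal(unname(fit$coefficients["x1"]),
               log(40 * 55 / (20 * 25)), tolerance = 1e-6)
  expect_equal(unname(fit$coefficients["(Intercept)"]),
               log(20 / 55), tolerance = 1e-6)
  # Wald SE oracle: sqrt(1/a + 1/b + 1/c + 1/d)
  expect_equal(unname(fit$se["x1"]),
               sqrt(1 / 40 + 1 / 20 + 1 / 25 + 1 / 55), tolerance = 1e-6)
  expect_true(fit$converged)
  expect_equal(unname(fit$wald["x1"]),
               unname((fit$coefficients["x1"] / fit$se["x1"])^2))
})

test_that("an uninformative predictor yields a null slope", {
  set.seed(41)
  coh <- data.frame(group = sample(c("case", "control"), 4000, TRUE),
                    x = sample(0:1, 4000, TRUE))
  fit <- fit_logistic(design_matrix(coh, "case", "x", binary_cb))
  expect_lt(abs(fit$coefficients["x1"]), 0.15)
  rate <- mean(coh$group == "case")
  expect_equal(unname(fit$coefficients["(Intercept)"]),
               log(rate / (1 - rate)), tolerance = 0.15)
})

test_that("separation is detected and rank deficiency is named", {
  coh <- cohort_from_counts(a = 50, b = 0, c = 0, d = 50)
  w <- capture_warnings(
    fit <- fit_logistic(design_matrix(coh, "case", "x", binary_cb)))
  expect_true(any(grepl("separation", w)))
  expect_true(fit$separation_flag)
  coh2 <- data.frame(group = rep(c("case", "control"), each = 50),
                     x = rep(0:1, 50), y = rep(0:1, 50))
  dm <- design_matrix(coh2, "case", c("x", "y"),
                      codebook(list(
                        variable_spec("x", "continuous", cutpoints = 1,
                                      bin_codes = 0:1),
                        variable_spec("y", "continuous", cutpoints = 1,
                                      bin_codes = 0:1))))
  expect_error(fit_logistic(dm), "collinear")
})

test_that("likelihood-ratio test behaves on nested fits", {
  coh <- small_cohort()
  full <- fit_logistic(design_matrix(coh, "T2DM", c("age", "sex")))
  red <- fit_logistic(design_matrix(coh, "T2DM", "age"))
  none <- fit_logistic(design_matrix(coh, "T2DM", character()))
  same <- lr_test(full, full)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  tr <- lr_test(full, red)
  expect_gte(tr$statistic, 0)
  expect_identical(tr$df, 1)
  expect_gte(lr_test(red, none)$statistic, 0)
  expect_error(lr_test(red, full), "not nested")
})

test_that("a strong simulated effect is detected with high power", {
  set.seed(43)
  hits <- 0L
  for (i in 1:20) {
    x <- stats::rnorm(1000)
    p <- stats::plogis(-0.3 + log(3) * x)
    coh <- data.frame(group = ifelse(stats::runif(1000) < p, "case",
                                     "control"), x = x)
    cb <- codebook(list(variable_spec("x", "continuous", cutpoints = 0,
                                      bin_codes = 0:1)))
    full <- fit_logistic(design_matrix(coh, "case", "x", cb))
    none <- fit_logistic(design_matrix(coh, "case", character(), cb))
    hits <- hits + as.integer(lr_test(full, none)$p_value < 0.001)
  }
  expect_gte(hits, 19L)
})

test_that("stepwise selection enters the dominant predictor first", {
  set.seed(44)
  n <- 1500
  strong <- stats::rnorm(n)
  weak <- stats::rnorm(n)
  noise <- stats::rnorm(n)
  p <- stats::plogis(log(5) * strong + 0.3 * weak)
  coh <- data.frame(group = ifelse(stats::runif(n) < p, "case", "control"),
                    strong = strong, weak = weak, noise = noise)
  cb <- codebook(lapply(c("strong", "weak", "noise"), function(nm)
    variable_spec(nm, "continuous", cutpoints = 0, bin_codes = 0:1)))
  sw <- stepwise_forward_lr(coh, "case", c("noise", "weak", "strong"), cb)
  expect_identical(sw$trace$variable[1], "strong")
  expect_identical(sw$trace$action[1], "enter")
  # brute force: the step-1 entry must have the largest LR statistic
  none <- fit_logistic(design_matrix(coh, "case", character(), cb))
  lrs <- vapply(c("noise", "weak", "strong"), function(v)
    lr_test(fit_logistic(design_matrix(coh, "case", v, cb)),
            none)$statistic, numeric(1))
  expect_identical(names(which.max(lrs)), "strong")
})

test_that("stepwise respects thresholds and degenerate settings", {
  coh <- small_cohort()
  cands <- c("age", "sex", "education")
  none <- stepwise_forward_lr(coh, "T2DM", cands, p_enter = 0)
  expect_length(none$selected, 0L)
  expect_identical(nrow(none$trace), 0L)

  # forcing every candidate in can push sparse education levels toward
  # separation on the reduced cohort; that warning is expected here
  all_in <- suppressWarnings(stepwise_forward_lr(coh, "T2DM", cands,
                                                 p_enter = 1, p_remove = 1))
  expect_setequal(all_in$selected, cands)
  full <- suppressWarnings(fit_logistic(design_matrix(coh, "T2DM", cands)))
  expect_equal(all_in$fit$loglik, full$loglik, tolerance = 1e-8)
})

test_that("a null candidate set yields the intercept-only model", {
  # with two null candidates tested at 0.05 the intercept-only rate is
  # about 0.90; 100 replicates keep the check away from binomial noise
  set.seed(45)
  empty <- 0L
  cb <- codebook(list(
    variable_spec("x", "continuous", cutpoints = 0, bin_codes = 0:1),
    variable_spec("z", "categorical", states = c(no = 0, yes = 1))))
  for (i in 1:100) {
    coh <- data.frame(group = sample(c("case", "control"), 400, TRUE),
                      x = stats::rnorm(400), z = sample(0:1, 400, TRUE))
    sw <- stepwise_forward_lr(coh, "case", c("x", "z"), cb)
    empty <- empty + as.integer(length(sw$selected) == 0L)
  }
  expect_gte(empty, 85L)
})

test_that("odds ratios reproduce the published interval arithmetic", {
  fake <- structure(list(
    coefficients = c(`(Intercept)` = -1, fhx_dm1 = 1.617),
    se = c(`(Intercept)` = 0.2, fhx_dm1 = 0.226),
    p_value = c(0.01, 1e-12), wald = c(25, 51.19)),
    class = "logistic_fit")
  tab <- odds_ratios(fake)
  expect_equal(tab$or, exp(1.617), tolerance = 1e-9)        # 5.038
  expect_equal(tab$or, 5.040, tolerance = 0.001)
  expect_equal(tab$ci_lower, 3.235, tolerance = 0.001)
  expect_equal(tab$ci_upper, 7.852, tolerance = 0.001)
  expect_equal(tab$wald_chi2, 51.136, tolerance = 0.002)
  # reciprocal reporting reverses the reference level
  expect_equal(1 / 0.110, 9.091, tolerance = 0.001)

  null_fit <- structure(list(coefficients = c(x = 0), se = c(x = 0.3),
                             p_value = 1, wald = 0),
                        class = "logistic_fit")
  tab0 <- odds_ratios(null_fit)
  expect_equal(tab0$or, 1)
  expect_lt(tab0$ci_lower, 1)
  expect_gt(tab0$ci_upper, 1)
})

test_that("categorical blocks enter as whole indicator sets", {
  coh <- small_cohort()
  sw <- stepwise_forward_lr(coh, "T2DM", c("education", "age"))
  if ("education" %in% sw$selected) {
    ors <- odds_ratios(sw$fit)
    expect_identical(sum(grepl("^education", ors$term)), 2L)
  }
  # the trace tests variables, not single indicators
  expect_true(all(sw$trace$variable %in% c("education", "age")))
})
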