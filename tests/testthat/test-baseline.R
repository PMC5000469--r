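binary_spec <- function(var = "country") {
  baseline_model_spec(blocks = list(main = var))
}

test_that("a one-binary-covariate fit equals the closed-form crude log OR", {
  # country a: 12/40 withdrawn; country b: 9/60 withdrawn
  co <- tiny_cohort(
    age = rep(30, 100),
    country = rep(c("a", "b"), c(40, 60)),
    events = rep(0, 100),
    withdrawn = c(rep(1, 12), rep(0, 28), rep(1, 9), rep(0, 51))
  )
  fit <- fit_logistic_baseline(co, binary_spec())
  est <- fit$coefficients$estimate[fit$coefficients$term == "countryb"]
  or <- crude_odds_ratio(contingency_cell("b", 51, 9),
                         contingency_cell("a", 28, 12))
  expect_equal(est, or$log_or, tolerance = 1e-8)
  expect_equal(fit$coefficients$odds_ratio[2], exp(est))
  expect_equal(fit$n_used, 100)
})

test_that("the intercept-only model recovers the logit of the overall rate", {
  co <- tiny_cohort(age = rep(30, 50), country = rep("a", 50),
                    events = rep(0, 50),
                    withdrawn = rep(c(1L, 0L), c(10, 40)))
  fit <- fit_logistic_baseline(co, baseline_model_spec(blocks = list()))
  expect_equal(fit$coefficients$estimate[1], qlogis(0.2), tolerance = 1e-8)
  expect_equal(fit$df, 0)
})

test_that("generating coefficients are recovered within three standard errors", {
  with_seed(31, {
    n <- 20000
    df <- tibble::tibble(
      age = runif(n, 15, 50),
      country = sample(c("a", "b"), n, replace = TRUE),
      events = rpois(n, 1.5)
    )
    truth <- c(intercept = -2, age = 0.04, countryb = 0.5, events = -0.2)
    eta <- truth["intercept"] + truth["age"] * df$age +
      truth["countryb"] * (df$country == "b") + truth["events"] * df$events
    df$withdrawn <- rbinom(n, 1, plogis(eta))
  })
  co <- as_cohort(df, tiny_schema())
  spec <- baseline_model_spec(blocks = list(all = c("age", "country", "events")),
                              references = c(country = "a"))
  fit <- fit_logistic_baseline(co, spec)
  cf <- fit$coefficients
  got <- setNames(cf$estimate, cf$term)
  for (term in c("age", "countryb", "events")) {
    se <- cf$se[cf$term == term]
    expect_lt(abs(got[term] - truth[term]), 3 * se)
  }
  expect_gt(fit$model_chisq, 0)
  expect_lt(fit$p_model, 1e-10)
})

test_that("complete cases and blockwise likelihood behave as specified", {
  spec <- teddy_like_spec(4000, seed = 17)
  co <- generate_cohort(spec)
  fit <- fit_logistic_baseline(co)
  # recount oracle: complete cases over the modeled covariates only
  modeled <- tibble::as_tibble(co)[, fit$spec$terms]
  expect_equal(fit$n_used, sum(stats::complete.cases(modeled)))
  expect_equal(fit$n_used + fit$n_dropped, nrow(co))
  # staged entry never decreases the in-sample log-likelihood
  expect_true(all(diff(fit$blocks$log_lik) >= -1e-8))
  # Wald report structure mirrors the model
  expect_true(all(fit$coefficients$conf_low <= fit$coefficients$conf_high))
  expect_equal(fit$coefficients$odds_ratio, exp(fit$coefficients$estimate))
  interaction_terms <- grep(":", fit$coefficients$term, value = TRUE)
  expect_equal(length(interaction_terms), 1)  # anxiety x risk perception
})

test_that("separation raises an explicit error naming the runaway term", {
  co <- tiny_cohort(age = c(rep(20, 20), rep(40, 20)),
                    country = rep("a", 40), events = rep(0, 40),
                    withdrawn = rep(c(1L, 0L), c(20, 20)))
  expect_error(
    fit_logistic_baseline(co, baseline_model_spec(blocks = list(m = "age"))),
    class = "cohortrules_separation_error", regexp = "age"
  )
})

test_that("too few complete cases is a loud failure", {
  co <- tiny_cohort(age = c(20, 30, 40), country = c("a", "b", "a"),
                    events = 0:2, withdrawn = c(1, 0, 1))
  expect_error(fit_logistic_baseline(co, binary_spec()),
               class = "cohortrules_value_error")
})

test_that("factor concordance flags rule-only and regression-only factors", {
  spec <- teddy_like_spec(5000, seed = 19)
  co <- generate_cohort(spec)
  fit <- fit_logistic_baseline(co)
  cmp <- compare_with_rules(fit, teddy_rules())
  expect_true(all(c("covariate", "in_regression", "in_rules", "flag") %in% names(cmp)))
  # negative life events appear only inside a rule, never as a model term
  expect_equal(cmp$flag[cmp$covariate == "negative_life_events"], "rule_only")
  # child sex is modeled but no packaged rule uses it
  expect_false(cmp$in_rules[cmp$covariate == "child_sex"])
  conc <- attr(cmp, "concordance")
  expect_true(conc >= 0 && conc <= 1)

  # identical factor sets give concordance 1
  fake_fit <- fit
  fake_fit$spec <- baseline_model_spec(blocks = list(m = "maternal_age"))
  fake_fit$coefficients <- tibble::tibble(
    term = c("(Intercept)", "maternal_age"), estimate = c(0, -1),
    se = c(1, 0.1), statistic = c(0, -10), p_value = c(1, 1e-8),
    odds_ratio = exp(c(0, -1)), conf_low = c(0.5, 0.2), conf_high = c(2, 0.6)
  )
  only_age <- rules_tibble(list(r1 = rule(rule_condition("maternal_age", "<", 27.5))))
  cmp2 <- compare_with_rules(fake_fit, only_age)
  expect_equal(attr(cmp2, "concordance"), 1)
})
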