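test_that("the generator is deterministic and honours n = 0", {
  spec <- one_rule_spec(0)
  expect_equal(nrow(generate_cohort(spec)), 0)

  spec <- one_rule_spec(500, seed = 9)
  co1 <- generate_cohort(spec)
  co2 <- generate_cohort(spec)
  expect_identical(co1, co2)
  spec2 <- one_rule_spec(500, seed = 10)
  expect_false(identical(generate_cohort(spec2), co1))
})

test_that("spec validation rejects malformed marginals and missingness", {
  s <- tiny_schema()
  marg <- list(age = list(mean = 30, sd = 5), country = c(a = 0.5, b = 0.6),
               events = list(lambda = 1))
  expect_error(synthetic_spec(s, 10, marg, 0), class = "cohortrules_spec_error")
  marg$country <- c(a = 0.4, b = 0.6)
  expect_error(synthetic_spec(s, 10, marg, 0, missingness = c(age = 1.5)),
               class = "cohortrules_spec_error")
  expect_error(synthetic_spec(s, -1, marg, 0), class = "cohortrules_spec_error")
  expect_error(synthetic_spec(s, 10, marg[-1], 0), class = "cohortrules_spec_error")
})

test_that("with no planted rules the empirical rate matches the baseline", {
  spec <- one_rule_spec(50000, seed = 3, with_rule = FALSE)
  co <- generate_cohort(spec)
  p <- 0.2
  se <- sqrt(p * (1 - p) / nrow(co))
  expect_lt(abs(mean(co$withdrawn) - p), 3 * se)
})

test_that("endorsers of a planted rule withdraw at the logit-shifted rate", {
  spec <- one_rule_spec(50000, seed = 5, effect = 1.0)
  co <- generate_cohort(spec)
  endo <- co$age < 27.5
  target <- plogis(qlogis(0.2) + 1.0)   # ~0.405
  n_e <- sum(endo)
  se <- sqrt(target * (1 - target) / n_e)
  expect_lt(abs(mean(co$withdrawn[endo]) - target), 3 * se)
  base_se <- sqrt(0.2 * 0.8 / sum(!endo))
  expect_lt(abs(mean(co$withdrawn[!endo]) - 0.2), 3 * base_se)
})

test_that("planted truth is analytic where independence allows", {
  spec0 <- one_rule_spec(100, with_rule = FALSE)
  pt0 <- planted_truth(spec0)
  expect_equal(attr(pt0, "overall_rate"), 0.2, tolerance = 1e-12)

  spec1 <- one_rule_spec(100, effect = 1.0)
  pt1 <- planted_truth(spec1)
  expect_equal(pt1$method, "analytic")
  expect_equal(pt1$expected_rate, plogis(qlogis(0.2) + 1))
  # truncated-normal endorsement probability for age < 27.5
  trunc_p <- function(q) {
    (pnorm(q, 30, 5) - pnorm(15, 30, 5)) / (pnorm(50, 30, 5) - pnorm(15, 30, 5))
  }
  expect_equal(pt1$endorsement_prob, trunc_p(27.5), tolerance = 1e-9)

  # two-condition rule on independent covariates: probability is a product
  s <- tiny_schema()
  two <- tibble::tibble(
    rule_id = "two", effect = 0.5,
    rule = list(rule(rule_condition("age", "<", 27.5),
                     rule_condition("country", "in", "a")))
  )
  spec2 <- synthetic_spec(
    s, 100,
    marginals = list(age = list(mean = 30, sd = 5), country = c(a = 0.4, b = 0.6),
                     events = list(lambda = 1)),
    baseline_logit = qlogis(0.2), planted_rules = two, seed = 1
  )
  pt2 <- planted_truth(spec2)
  expect_equal(pt2$endorsement_prob, trunc_p(27.5) * 0.4, tolerance = 1e-9)

  # Monte Carlo agreement with the analytic product
  co <- generate_cohort(synthetic_spec(
    s, 40000,
    marginals = list(age = list(mean = 30, sd = 5), country = c(a = 0.4, b = 0.6),
                     events = list(lambda = 1)),
    baseline_logit = qlogis(0.2), planted_rules = two, seed = 2
  ))
  emp <- mean(endorse(two$rule[[1]], co))
  expect_lt(abs(emp - pt2$endorsement_prob), 3 * sqrt(emp * (1 - emp) / 40000))
})

test_that("masking covariate cells never alters the outcome vector", {
  s <- tiny_schema()
  marg <- list(age = list(mean = 30, sd = 5), country = c(a = 0.4, b = 0.6),
               events = list(lambda = 1))
  planted <- tibble::tibble(rule_id = "r", effect = 1,
                            rule = list(rule(rule_condition("age", "<", 28))))
  clean <- synthetic_spec(s, 2000, marg, qlogis(0.2), planted, seed = 11)
  masked <- synthetic_spec(s, 2000, marg, qlogis(0.2), planted,
                           missingness = c(country = 0.3, events = 0.2), seed = 11)
  co_clean <- generate_cohort(clean)
  co_masked <- generate_cohort(masked)
  expect_identical(co_clean$withdrawn, co_masked$withdrawn)
  expect_no_na(co_masked$withdrawn)
  expect_gt(sum(is.na(co_masked$country)), 0)
})

test_that("generated marginals converge to the spec distributions", {
  spec <- teddy_like_spec(100000, seed = 21)
  co <- generate_cohort(spec)

  # categorical: chi-square against spec probabilities at alpha = 0.001
  for (v in c("country", "smoked", "risk_perception")) {
    probs <- spec$marginals[[v]]
    obs <- table(factor(co[[v]], levels = names(probs)))
    expect_gt(stats::chisq.test(obs, p = probs)$p.value, 0.001)
  }
  # continuous: KS against the truncated normal, alpha = 0.001
  m <- spec$marginals$maternal_age
  plo <- pnorm(15, m$mean, m$sd); phi <- pnorm(50, m$mean, m$sd)
  cdf <- function(q) (pnorm(q, m$mean, m$sd) - plo) / (phi - plo)
  ks <- stats::ks.test(co$maternal_age, cdf)
  expect_gt(ks$p.value, 0.001)

  # missingness rates near the published fractions
  expect_equal(mean(is.na(co$smoked)), 178 / 3757, tolerance = 0.15)
  expect_equal(mean(is.na(co$worked_all_trimesters)), 245 / 3757, tolerance = 0.15)
})

test_that("the ready-made cohort hits its calibrated overall withdrawal rate", {
  spec <- teddy_like_spec(3757, seed = 4)
  co <- generate_cohort(spec)
  target <- 763 / 3757
  se <- sqrt(target * (1 - target) / nrow(co))
  expect_lt(abs(mean(co$withdrawn) - target), 3 * se)

  # endorsers of a planted risk-increasing rule withdraw more than average
  big <- generate_cohort(teddy_like_spec(20000, seed = 5))
  r1 <- teddy_rules()$rule[[1]]
  expect_gt(mean(big$withdrawn[endorse(r1, big)]), mean(big$withdrawn))
})

test_that("spec YAML round-trip preserves the generative model", {
  spec <- one_rule_spec(123, seed = 8)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_spec_yaml(spec, path)
  spec2 <- read_spec_yaml(path, tiny_schema())
  expect_equal(spec2$n, spec$n)
  expect_equal(spec2$baseline_logit, spec$baseline_logit)
  expect_equal(spec2$missingness, spec$missingness)
  expect_identical(generate_cohort(spec2), generate_cohort(spec))
})
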