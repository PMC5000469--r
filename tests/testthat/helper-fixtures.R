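# Small in-code fixtures shared across tests.

tiny_schema <- function() {
  covariate_schema(tibble::tibble(
    variable = c("age", "country", "events"),
    kind = c("continuous", "categorical", "count"),
    levels = list(NULL, c("a", "b"), NULL),
    min = c(15, NA, 0), max = c(50, NA, Inf)
  ))
}

tiny_cohort <- function(age, country, events, withdrawn,
                        schema = tiny_schema()) {
  as_cohort(tibble::tibble(age = age, country = country,
                           events = events, withdrawn = withdrawn),
            schema)
}

# A simple one-covariate synthetic spec used for generator closed forms.
one_rule_spec <- function(n, seed = 1L, effect = 1.0,
                          base_rate = 0.2, with_rule = TRUE) {
  schema <- tiny_schema()
  planted <- NULL
  if (with_rule) {
    planted <- tibble::tibble(
      rule_id = "young",
      effect = effect,
      rule = list(rule(rule_condition("age", "<", 27.5)))
    )
  }
  synthetic_spec(
    schema, n,
    marginals = list(age = list(mean = 30, sd = 5),
                     country = c(a = 0.4, b = 0.6),
                     events = list(lambda = 1)),
    baseline_logit = qlogis(base_rate),
    planted_rules = planted, seed = seed
  )
}

# Random rule over a cohort's covariates; by construction independent of the
# outcome when the generating spec plants no effects.
random_noise_rule <- function(schema, cohort) {
  repeat {
    v <- sample(schema$variable, 1)
    i <- match(v, schema$variable)
    if (schema$kind[i] == "categorical") {
      lev <- sample(schema$levels[[i]], 1)
      return(rule(rule_condition(v, "in", lev)))
    }
    x <- cohort[[v]]
    x <- x[!is.na(x)]
    if (length(unique(x)) < 3) next
    thr <- unname(quantile(x, runif(1, 0.2, 0.8), type = 1))
    op <- sample(c("<", ">="), 1)
    return(rule(rule_condition(v, op, thr)))
  }
}

expect_no_na <- function(x) expect_false(anyNA(x))
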