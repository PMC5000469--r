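test_that("rule text round-trips through parse and format", {
  s <- teddy_schema()
  texts <- c(
    "maternal_age < 27.5 AND country != finland",
    "smoked = yes AND anxiety_score > 45",
    "country in {finland, germany} AND negative_life_events < 2",
    "alcohol_3rd_trimester != none",
    "missing_count <= 1"
  )
  for (tx in texts) {
    r <- parse_rule(tx, s)
    expect_equal(format_rule(r, s), tx)
  }
  expect_error(parse_rule("maternal_age ~ 3", s), class = "cohortrules_rule_error")
  expect_error(parse_rule("country = mars", s), class = "cohortrules_rule_error")
  expect_error(parse_rule("country < 3", s), class = "cohortrules_rule_error")
})

test_that("simplification keeps the tightest interval per feature", {
  s <- tiny_schema()
  r <- rule(rule_condition("age", "<", 27.5), rule_condition("age", "<", 25))
  rs <- simplify_rule(r, s)
  expect_equal(nrow(rs$conditions), 1)
  expect_equal(rs$conditions$value[[1]], 25)

  # oracle: simplified rule endorses exactly the same records
  co <- tiny_cohort(age = seq(16, 49, length.out = 40),
                    country = rep(c("a", "b"), 20),
                    events = rep(0:3, 10), withdrawn = rep(0:1, 20))
  r2 <- rule(rule_condition("age", ">=", 20), rule_condition("age", "<", 30),
             rule_condition("age", ">=", 24), rule_condition("country", "in", "a"))
  expect_equal(endorse(simplify_rule(r2, s), co), endorse(r2, co))

  # contradiction: empty interval endorses nobody
  r3 <- simplify_rule(rule(rule_condition("age", "<", 20),
                           rule_condition("age", ">=", 30)), s)
  expect_true(attr(r3, "infeasible"))
  expect_false(any(endorse(r3, co)))

  # intersecting level sets; full level set is vacuous and dropped
  r4 <- simplify_rule(rule(rule_condition("country", "in", c("a", "b")),
                           rule_condition("age", "<", 30)), s)
  expect_equal(r4$conditions$feature, "age")
})

test_that("endorsement is the conjunction of conditions and missing is false", {
  s <- teddy_schema()
  # six hand-built records against the anxious-mother / absent-father rule
  df <- tibble::tibble(
    anxiety_score = c(50, 50, 40, NA, 46, 45),
    dad_participation = c("no", "yes", "no", "no", NA, "no")
  )
  r <- parse_rule("anxiety_score > 45 AND dad_participation = no", s)
  expect_equal(endorse(r, df), c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE))
})

test_that("the endorsement matrix has one binary column per rule", {
  co <- tiny_cohort(age = c(20, 30, 40), country = c("a", "b", "a"),
                    events = c(0, 1, 5), withdrawn = c(1, 0, 0))
  s <- tiny_schema()
  expect_equal(dim(endorsement_matrix(list(), co)), c(3, 0))

  r <- parse_rule("age < 25", s)
  m <- endorsement_matrix(list(a = r, b = r), co)
  expect_equal(m[, "a"], m[, "b"])  # duplicates produce identical columns
  expect_true(all(m %in% c(0L, 1L)))

  bad <- rule(rule_condition("nope", "<", 1))
  expect_error(endorsement_matrix(list(bad), co),
               class = "cohortrules_schema_error")
})

test_that("endorsement jaccard handles empty and identical patterns", {
  expect_equal(endorsement_jaccard(c(1, 1, 0), c(1, 1, 0)), 1)
  expect_equal(endorsement_jaccard(c(0, 0), c(0, 0)), 1)
  expect_equal(endorsement_jaccard(c(1, 0), c(0, 1)), 0)
  expect_equal(endorsement_jaccard(c(1, 1, 0, 0), c(1, 0, 1, 0)), 1 / 3)
})

test_that("the packaged rule fixture has eight rules with signed directions", {
  rules <- teddy_rules()
  expect_equal(nrow(rules), 8)
  expect_equal(sum(rules$direction == "increasing"), 4)
  expect_equal(sum(rules$direction == "decreasing"), 4)
  # maternal age 27.5 and the anxiety cutoff 45 appear as printed
  feats <- purrr::map(rules$rule, ~ .x$conditions)
  age_thr <- purrr::map_dbl(feats, function(cc) {
    i <- which(cc$feature == "maternal_age")
    if (length(i) == 0) NA_real_ else cc$value[[i[1]]]
  })
  expect_true(all(stats::na.omit(age_thr) == 27.5))

  # round-trip through the serialized form preserves semantics and labels
  # (the text form may re-express a level set in its canonical sugar)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_rules(rules, path, schema = teddy_schema())
  again <- read_rules(path, teddy_schema())
  expect_equal(again$direction, rules$direction)
  co <- generate_cohort(teddy_like_spec(500, seed = 1))
  expect_equal(unname(endorsement_matrix(again, co)),
               unname(endorsement_matrix(rules, co)))
})
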