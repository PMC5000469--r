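test_that("a rule endorsed by everyone profiles at the overall rate", {
  co <- tiny_cohort(age = c(20, 30, 40, 50 - 1e-9), country = rep("a", 4),
                    events = rep(0, 4), withdrawn = c(1, 0, 1, 0))
  r <- rule(rule_condition("age", "<", 100))
  prof <- profile_rules(list(everyone = r), co)
  p <- prof$profiles
  expect_equal(p$n_endorsing, 4)
  expect_equal(p$outcome_rate, prof$overall_rate)
  expect_equal(p$rate_ratio_vs_overall, 1)
  expect_equal(p$direction, "neutral")
  expect_equal(prof$coverage$fraction_uncovered, 0)
})

test_that("hand-counted subgroup rates are reproduced exactly", {
  co <- tiny_cohort(age = c(20, 21, 22, 23, 35, 36, 37, 38, 39, 40),
                    country = rep(c("a", "b"), 5), events = rep(0, 10),
                    withdrawn = c(1, 1, 1, 0, 0, 0, 1, 0, 0, 0))
  r <- rule(rule_condition("age", "<", 25))  # endorsed by 4, of which 3 withdrew
  prof <- profile_rules(list(young = r), co)
  expect_equal(prof$profiles$n_endorsing, 4)
  expect_equal(prof$profiles$outcome_rate, 0.75)
  expect_equal(prof$profiles$direction, "increasing")
  expect_equal(prof$coverage$n_uncovered, 6)
  expect_equal(prof$coverage$uncovered_outcome_rate, 1 / 6)
})

test_that("zero-endorser rules are flagged undefined, never silent zeros", {
  co <- tiny_cohort(age = c(30, 40), country = c("a", "b"),
                    events = c(0, 1), withdrawn = c(0, 1))
  r <- rule(rule_condition("age", "<", 16))
  prof <- profile_rules(list(nobody = r), co)
  expect_equal(prof$profiles$n_endorsing, 0)
  expect_true(is.na(prof$profiles$outcome_rate))
  expect_equal(prof$profiles$direction, "undefined")
})

test_that("covered and uncovered strata mix back to the overall rate", {
  spec <- teddy_like_spec(4000, seed = 12)
  co <- generate_cohort(spec)
  rules <- teddy_rules()
  prof <- profile_rules(rules, co)
  E <- endorsement_matrix(rules, co)
  covered <- rowSums(E) > 0
  n <- nrow(co)
  mix <- mean(covered) * mean(co$withdrawn[covered]) +
    prof$coverage$fraction_uncovered * prof$coverage$uncovered_outcome_rate
  expect_equal(mix, prof$overall_rate, tolerance = 1e-12)
  # union of per-rule withdrawals plus uncovered withdrawals = total
  expect_equal(sum(co$withdrawn[covered]) + sum(co$withdrawn[!covered]),
               sum(co$withdrawn))
})

test_that("profile directions are invariant to record and rule order", {
  spec <- teddy_like_spec(1200, seed = 13)
  co <- generate_cohort(spec)
  rules <- teddy_rules()
  p1 <- profile_rules(rules, co)$profiles
  perm_rows <- with_seed(1, sample(nrow(co)))
  co2 <- as_cohort(tibble::as_tibble(co)[perm_rows, ], teddy_schema())
  perm_rules <- c(5, 3, 8, 1, 2, 7, 4, 6)
  p2 <- profile_rules(rules[perm_rules, ], co2)$profiles
  merged <- dplyr::left_join(p1, p2, by = "rule_id", suffix = c("", ".2"))
  expect_equal(merged$direction, merged$direction.2)
  expect_equal(merged$n_endorsing, merged$n_endorsing.2)
})

test_that("redundancy entries equal brute-force set intersections", {
  # eight hand records, three overlapping rules
  co <- tiny_cohort(age = c(20, 22, 24, 26, 33, 35, 37, 39),
                    country = c("a", "a", "b", "b", "a", "a", "b", "b"),
                    events = c(0, 1, 2, 3, 0, 1, 2, 3),
                    withdrawn = c(1, 0, 1, 0, 1, 0, 1, 0))
  rules <- list(
    young = rule(rule_condition("age", "<", 27)),
    a_land = rule(rule_condition("country", "in", "a")),
    calm = rule(rule_condition("events", "<", 2))
  )
  rm <- redundancy_matrix(rules, co)
  sets <- list(young = 1:4, a_land = c(1, 2, 5, 6), calm = c(1, 2, 5, 6))
  for (i in names(sets)) {
    for (j in names(sets)) {
      expect_equal(rm$M[i, j],
                   length(intersect(sets[[i]], sets[[j]])) / length(sets[[i]]))
    }
  }
  expect_true(all(diag(rm$M) == 1))

  # mutually exclusive rules share nobody
  excl <- list(lo = rule(rule_condition("age", "<", 27.5)),
               hi = rule(rule_condition("age", ">=", 27.5)))
  rm2 <- redundancy_matrix(excl, co)
  expect_equal(rm2$M["lo", "hi"], 0)
  expect_equal(rm2$M["hi", "lo"], 0)
})

test_that("joint-count symmetry is an exact integer identity", {
  for (seed in 1:5) {
    co <- generate_cohort(teddy_like_spec(600, seed = seed))
    rules <- with_seed(seed, purrr::map(1:6, ~ random_noise_rule(teddy_schema(), co)))
    names(rules) <- paste0("r", 1:6)
    rm <- redundancy_matrix(rules, co)
    # the joint endorsement counts are integers and exactly symmetric
    expect_identical(unclass(rm$joint), t(unclass(rm$joint)))
    q <- nrow(rm$M)
    for (i in seq_len(q)) {
      for (j in seq_len(q)) {
        if (rm$n_endorsing[i] > 0 && rm$n_endorsing[j] > 0) {
          expect_equal(unname(rm$M[i, j] * rm$n_endorsing[i]),
                       unname(rm$M[j, i] * rm$n_endorsing[j]),
                       tolerance = 1e-12)
          expect_equal(unname(rm$M[i, j] * rm$n_endorsing[i]),
                       unname(rm$joint[i, j]), tolerance = 1e-12)
        }
      }
    }
  }
})

test_that("reports round-trip through CSV and cover the empty case", {
  out <- withr::local_tempdir()
  spec <- teddy_like_spec(800, seed = 14)
  co <- generate_cohort(spec)
  rules <- teddy_rules()
  prof <- profile_rules(rules, co)
  rm <- redundancy_matrix(rules, co)
  files <- render_reports(prof, rm, out, plots = FALSE)
  back <- readr::read_csv(file.path(out, "subgroup_profiles.csv"),
                          show_col_types = FALSE)
  expect_equal(back$outcome_rate, prof$profiles$outcome_rate)
  mat <- readr::read_csv(file.path(out, "redundancy_matrix.csv"),
                         show_col_types = FALSE)
  expect_equal(dim(as.matrix(mat[, -1])), c(8, 8))

  empty <- profile_rules(list(), co)
  render_reports(empty, NULL, out, plots = FALSE)
  hdr <- readr::read_csv(file.path(out, "subgroup_profiles.csv"),
                         show_col_types = FALSE)
  expect_equal(nrow(hdr), 0)
})
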