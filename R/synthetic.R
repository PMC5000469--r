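#' Specify a synthetic withdrawal cohort
#'
#' A synthetic spec fixes everything needed to generate a cohort with the
#' statistical structure the rule pipeline assumes: per-covariate marginal
#' distributions, a logistic outcome model with planted rule effects, and
#' per-covariate missingness. Covariates are drawn independently; the
#' outcome of record *i* is Bernoulli with
#' `logit p_i = baseline_logit + sum of effects of the planted rules record
#' i endorses`. Planted effects add on the logit scale, matching the
#' additive rule model fitted by the pruning stage.
#'
#' The per-record missing-data count is itself a covariate: the missingness
#' mask is drawn *before* the outcome, the derived count enters rule
#' endorsement, and only then is the outcome drawn and the masked cells
#' blanked. Masking therefore never alters outcomes, while rules that
#' condition on the missing-data count remain generatively meaningful.
#'
#' @param schema A [covariate_schema()].
#' @param n Cohort size (>= 0).
#' @param marginals Named list, one entry per non-derived covariate:
#'   categorical — a probability vector named by level (sums to 1);
#'   continuous — `list(mean =, sd =)` (truncated to the schema range);
#'   count — `list(lambda =)` (Poisson).
#' @param baseline_logit Log-odds of withdrawal when no planted rule fires.
#' @param planted_rules A tibble with list column `rule` and numeric column
#'   `effect` (log-odds increments), e.g. [teddy_rules()] plus effects;
#'   or `NULL` for no planted structure.
#' @param missingness Named numeric vector of per-covariate missing
#'   probabilities in \[0, 1\]; covariates not named are never missing.
#' @param seed Integer seed; the generator is fully reproducible from it.
#' @return A `synthetic_spec` object.
#' @export
synthetic_spec <- function(schema, n, marginals, baseline_logit,
                           planted_rules = NULL, missingness = NULL,
                           seed = 1L) {
  if (n < 0) abort("n must be >= 0", class = "cohortrules_spec_error")
  base_vars <- schema$variable[!schema$derived]
  missing_marg <- setdiff(base_vars, names(marginals))
  if (length(missing_marg) > 0) {
    abort(paste0("marginals missing for: ", paste(missing_marg, collapse = ", ")),
          class = "cohortrules_spec_error")
  }
  for (v in base_vars) {
    kind <- schema_kind(schema, v)
    m <- marginals[[v]]
    if (kind == "categorical") {
      levs <- schema_levels(schema, v)
      if (!setequal(names(m), levs)) {
        abort(paste0("marginal for '", v, "' must be named by its levels"),
              class = "cohortrules_spec_error")
      }
      if (abs(sum(m) - 1) > 1e-9) {
        abort(paste0("level probabilities for '", v, "' must sum to 1"),
              class = "cohortrules_spec_error")
      }
    } else if (kind == "continuous") {
      if (!all(c("mean", "sd") %in% names(m)) || m$sd <= 0) {
        abort(paste0("continuous marginal for '", v, "' needs mean and sd > 0"),
              class = "cohortrules_spec_error")
      }
    } else {
      if (!"lambda" %in% names(m) || m$lambda < 0) {
        abort(paste0("count marginal for '", v, "' needs lambda >= 0"),
              class = "cohortrules_spec_error")
      }
    }
  }
  miss <- setNames(rep(0, length(base_vars)), base_vars)
  if (!is.null(missingness)) {
    extra <- setdiff(names(missingness), base_vars)
    if (length(extra) > 0) {
      abort(paste0("missingness names unknown: ", paste(extra, collapse = ", ")),
            class = "cohortrules_spec_error")
    }
    if (any(missingness < 0 | missingness > 1)) {
      abort("missingness probabilities must lie in [0, 1]",
            class = "cohortrules_spec_error")
    }
    miss[names(missingness)] <- missingness
  }
  if (!is.null(planted_rules)) {
    stopifnot(is.data.frame(planted_rules),
              all(c("rule", "effect") %in% names(planted_rules)))
    planted_rules <- tibble::as_tibble(planted_rules)
    if (!"rule_id" %in% names(planted_rules)) {
      planted_rules$rule_id <- paste0("planted_", seq_len(nrow(planted_rules)))
    }
  }
  structure(
    list(schema = schema, n = as.integer(n), marginals = marginals,
         baseline_logit = baseline_logit, planted_rules = planted_rules,
         missingness = miss, seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat("<synthetic_spec> n = ", x$n,
      ", baseline logit = ", sprintf("%.3f", x$baseline_logit),
      " (rate ", sprintf("%.3f", plogis(x$baseline_logit)), ")",
      ", planted rules = ",
      if (is.null(x$planted_rules)) 0 else nrow(x$planted_rules),
      ", seed = ", x$seed, "\n", sep = "")
  invisible(x)
}

# Truncated-normal draw via inverse-CDF so truncation keeps the stream
# one-uniform-per-value (determinism independent of acceptance rates).
rtruncnorm_inv <- function(n, mean, sd, lo, hi) {
  plo <- pnorm(lo, mean, sd); phi <- pnorm(hi, mean, sd)
  qnorm(runif(n, plo, phi), mean, sd)
}

#' @importFrom stats pnorm ppois
draw_covariates <- function(spec) {
  schema <- spec$schema
  n <- spec$n
  out <- tibble::tibble(.rows = n)
  for (i in seq_len(nrow(schema))) {
    if (schema$derived[i]) next
    v <- schema$variable[i]
    m <- spec$marginals[[v]]
    out[[v]] <- switch(
      schema$kind[i],
      categorical = sample(names(m), n, replace = TRUE, prob = m),
      continuous = {
        lo <- schema$min[i]; hi <- schema$max[i]
        if (is.na(lo)) lo <- -Inf
        if (is.na(hi)) hi <- Inf
        rtruncnorm_inv(n, m$mean, m$sd, lo, hi)
      },
      count = rpois(n, m$lambda)
    )
  }
  out
}

#' Generate a synthetic cohort
#'
#' Draws covariates, the missingness mask, planted-rule endorsement (on the
#' complete covariate values plus the derived missing-data count) and the
#' Bernoulli outcome, in that order, each from an independent seeded
#' substream; then blanks the masked cells. Identical specs produce
#' identical cohorts.
#'
#' @param spec A [synthetic_spec()].
#' @return A cohort (see [as_cohort()]).
#' @export
generate_cohort <- function(spec) {
  schema <- spec$schema
  outcome <- schema_outcome(schema)
  n <- spec$n

  complete <- with_seed(derive_seed(spec$seed, "covariates"), draw_covariates(spec))
  base_vars <- names(complete)

  mask <- with_seed(derive_seed(spec$seed, "mask"), {
    m <- matrix(FALSE, nrow = n, ncol = length(base_vars),
                dimnames = list(NULL, base_vars))
    for (v in base_vars) {
      p <- spec$missingness[[v]]
      if (p > 0) m[, v] <- runif(n) < p
    }
    m
  })
  mc <- as.integer(rowSums(mask))

  gen_data <- complete
  for (i in which(schema$derived)) gen_data[[schema$variable[i]]] <- mc

  eta <- rep(spec$baseline_logit, n)
  if (!is.null(spec$planted_rules) && nrow(spec$planted_rules) > 0 && n > 0) {
    E <- endorsement_matrix(spec$planted_rules, gen_data)
    eta <- eta + as.numeric(E %*% spec$planted_rules$effect)
  }
  y <- with_seed(derive_seed(spec$seed, "outcome"),
                 rbinom(n, 1L, plogis(eta)))

  observed <- complete
  for (v in base_vars) observed[[v]][mask[, v]] <- NA
  observed[[outcome]] <- y
  as_cohort(observed, schema)
}

# P(condition holds) under the spec's independent marginals.
condition_probability <- function(cond, spec) {
  schema <- spec$schema
  f <- cond$feature
  v <- cond$value[[1]]
  kind <- schema_kind(schema, f)
  i <- match(f, schema$variable)
  if (schema$derived[i]) {
    # missing-data count: Poisson-binomial over per-covariate miss rates
    pmf <- poisson_binomial_pmf(spec$missingness)
    k <- seq_along(pmf) - 1
    sel <- switch(cond$op, "<" = k < v, "<=" = k <= v, ">" = k > v, ">=" = k >= v,
                  abort("level condition on a count covariate",
                        class = "cohortrules_rule_error"))
    return(sum(pmf[sel]))
  }
  m <- spec$marginals[[f]]
  if (kind == "categorical") {
    return(sum(m[v]))
  }
  if (kind == "continuous") {
    lo <- schema$min[i]; hi <- schema$max[i]
    if (is.na(lo)) lo <- -Inf
    if (is.na(hi)) hi <- Inf
    zlo <- pnorm(lo, m$mean, m$sd); zhi <- pnorm(hi, m$mean, m$sd)
    tr <- function(q) (pmin(pmax(pnorm(q, m$mean, m$sd), zlo), zhi) - zlo) / (zhi - zlo)
    return(switch(cond$op,
                  "<" = tr(v), "<=" = tr(v), ">" = 1 - tr(v), ">=" = 1 - tr(v)))
  }
  # Poisson count
  switch(cond$op,
         "<"  = ppois(ceiling(v) - 1, m$lambda),
         "<=" = ppois(floor(v), m$lambda),
         ">"  = 1 - ppois(floor(v), m$lambda),
         ">=" = 1 - ppois(ceiling(v) - 1, m$lambda))
}

poisson_binomial_pmf <- function(probs) {
  pmf <- 1
  for (p in probs) pmf <- c(pmf * (1 - p), 0) + c(0, pmf * p)
  pmf
}

#' Expected endorsement and risk of the planted rules
#'
#' Computes, for each planted rule, the expected fraction of the population
#' endorsing it and the expected withdrawal rate among endorsers, plus the
#' expected overall rate. Endorsement probabilities are analytic products
#' over the independent marginals (including the Poisson-binomial law of
#' the derived missing-data count). Conditional rates are analytic
#' (`expit(baseline + effect)`) only when a single rule is planted;
#' with overlapping rules they are estimated by Monte Carlo and flagged.
#'
#' @param spec A [synthetic_spec()].
#' @param mc_n Monte Carlo sample size for non-analytic quantities.
#' @return A tibble (`rule_id`, `effect`, `endorsement_prob`,
#'   `expected_rate`, `method`) with attribute `overall_rate`.
#' @export
planted_truth <- function(spec, mc_n = 200000) {
  rules <- spec$planted_rules
  if (is.null(rules) || nrow(rules) == 0) {
    out <- tibble::tibble(rule_id = character(), effect = numeric(),
                          endorsement_prob = numeric(),
                          expected_rate = numeric(), method = character())
    attr(out, "overall_rate") <- plogis(spec$baseline_logit)
    return(out)
  }
  endo_p <- purrr::map_dbl(rules$rule, function(r) {
    rs <- simplify_rule(r, spec$schema)
    if (isTRUE(attr(rs, "infeasible"))) return(0)
    prod(purrr::map_dbl(seq_len(nrow(rs$conditions)),
                        ~ condition_probability(rs$conditions[.x, ], spec)))
  })

  if (nrow(rules) == 1) {
    out <- tibble::tibble(
      rule_id = rules$rule_id, effect = rules$effect,
      endorsement_prob = endo_p,
      expected_rate = plogis(spec$baseline_logit + rules$effect),
      method = "analytic"
    )
    # overall = P(endorse) * rate_in + (1-P) * base
    attr(out, "overall_rate") <-
      endo_p * plogis(spec$baseline_logit + rules$effect) +
      (1 - endo_p) * plogis(spec$baseline_logit)
    return(out)
  }

  # overlapping rules: Monte Carlo on the generative model (no masking of
  # the evaluation data; endorsement semantics match generate_cohort)
  mc_spec <- spec
  mc_spec$n <- as.integer(mc_n)
  mc_spec$seed <- derive_seed(spec$seed, "planted_truth_mc")
  complete <- with_seed(derive_seed(mc_spec$seed, "covariates"),
                        draw_covariates(mc_spec))
  mask <- with_seed(derive_seed(mc_spec$seed, "mask"), {
    m <- matrix(FALSE, nrow = mc_n, ncol = ncol(complete),
                dimnames = list(NULL, names(complete)))
    for (v in names(complete)) {
      p <- spec$missingness[[v]]
      if (p > 0) m[, v] <- runif(mc_n) < p
    }
    m
  })
  gen_data <- complete
  for (i in which(spec$schema$derived)) {
    gen_data[[spec$schema$variable[i]]] <- as.integer(rowSums(mask))
  }
  E <- endorsement_matrix(rules, gen_data)
  p_i <- plogis(spec$baseline_logit + as.numeric(E %*% rules$effect))
  out <- tibble::tibble(
    rule_id = rules$rule_id, effect = rules$effect,
    endorsement_prob = endo_p,
    expected_rate = purrr::map_dbl(seq_len(ncol(E)), function(k) {
      sel <- E[, k] == 1
      if (!any(sel)) return(NA_real_)
      mean(p_i[sel])
    }),
    method = "mc"
  )
  attr(out, "overall_rate") <- mean(p_i)
  out
}

#' Ready-made spec emulating the TEDDY first-year withdrawal cohort
#'
#' Builds a [synthetic_spec()] whose categorical marginals, continuous
#' moments (maternal age 30.4 (5.2) years, anxiety 39.1 (9.9)) and
#' per-covariate missingness rates follow the published descriptive
#' statistics of the TEDDY actives/withdrawals sample, with the eight
#' packaged risk rules ([teddy_rules()]) planted at signed log-odds
#' effects matching their risk-increasing/decreasing labels. The baseline
#' log-odds is calibrated by Monte Carlo root-finding so the expected
#' overall withdrawal rate matches `target_rate` (default 763/3757 = 20.3%).
#'
#' @param n Cohort size.
#' @param seed Integer seed.
#' @param effect_size Absolute planted log-odds effect per rule.
#' @param target_rate Expected overall withdrawal rate.
#' @return A [synthetic_spec()].
#' @export
teddy_like_spec <- function(n, seed = 1L, effect_size = 1.0,
                            target_rate = 763 / 3757) {
  schema <- teddy_schema()
  marginals <- list(
    country = c(finland = 887, germany = 142, sweden = 1283, us = 1445) / 3757,
    child_sex = c(male = 1890, female = 1867) / 3757,
    maternal_age = list(mean = 30.4, sd = 5.2),
    smoked = c(no = 3112, yes = 467) / 3579,
    alcohol_3rd_trimester =
      c(none = 2968, monthly_1_2 = 546, monthly_3_plus = 118) / 3632,
    worked_all_trimesters = c(no = 1843, yes = 1669) / 3512,
    dad_participation = c(no = 320, yes = 3437) / 3757,
    risk_perception = c(underestimate = 1475, accurate = 2164) / 3639,
    anxiety_score = list(mean = 39.1, sd = 9.9),
    negative_life_events = list(lambda = 1.5)
  )
  missingness <- c(
    smoked = 178 / 3757, alcohol_3rd_trimester = 125 / 3757,
    worked_all_trimesters = 245 / 3757, risk_perception = 118 / 3757,
    anxiety_score = 109 / 3757
  )
  planted <- teddy_rules(schema)
  planted$effect <- ifelse(planted$direction == "increasing",
                           effect_size, -effect_size)

  spec <- synthetic_spec(schema, n, marginals, baseline_logit = qlogis(target_rate),
                         planted_rules = planted, missingness = missingness,
                         seed = seed)
  spec$baseline_logit <- calibrate_baseline_logit(spec, target_rate)
  spec
}

# Root-find the intercept so the expected overall rate hits the target,
# using one shared Monte Carlo endorsement sample. The calibration stream
# is fixed (independent of the spec seed) so every teddy_like_spec shares
# one intercept for a given effect size and target.
calibrate_baseline_logit <- function(spec, target_rate, mc_n = 50000) {
  cal_spec <- spec
  cal_spec$n <- as.integer(mc_n)
  cal_spec$seed <- derive_seed(760313, "baseline_calibration")
  complete <- with_seed(derive_seed(cal_spec$seed, "covariates"),
                        draw_covariates(cal_spec))
  mask_draw <- with_seed(derive_seed(cal_spec$seed, "mask"), {
    m <- matrix(FALSE, nrow = mc_n, ncol = ncol(complete),
                dimnames = list(NULL, names(complete)))
    for (v in names(complete)) {
      p <- spec$missingness[[v]]
      if (p > 0) m[, v] <- runif(mc_n) < p
    }
    m
  })
  gen_data <- complete
  for (i in which(spec$schema$derived)) {
    gen_data[[spec$schema$variable[i]]] <- as.integer(rowSums(mask_draw))
  }
  shift <- if (is.null(spec$planted_rules) || nrow(spec$planted_rules) == 0) {
    rep(0, mc_n)
  } else {
    E <- endorsement_matrix(spec$planted_rules, gen_data)
    as.numeric(E %*% spec$planted_rules$effect)
  }
  uniroot(function(b) mean(plogis(b + shift)) - target_rate,
          lower = qlogis(target_rate) - 6, upper = qlogis(target_rate) + 6,
          tol = 1e-8)$root
}

#' Serialize a synthetic spec to / from YAML
#'
#' Planted rules are stored in their text form.
#'
#' @param spec A [synthetic_spec()].
#' @param path File path.
#' @return `write_spec_yaml()` returns `path` invisibly;
#'   `read_spec_yaml()` a [synthetic_spec()].
#' @export
write_spec_yaml <- function(spec, path) {
  y <- list(
    n = spec$n, baseline_logit = spec$baseline_logit, seed = spec$seed,
    marginals = purrr::map(spec$marginals, function(m) {
      if (is.numeric(m) && !is.null(names(m))) as.list(m) else m
    }),
    missingness = as.list(spec$missingness[spec$missingness > 0])
  )
  if (!is.null(spec$planted_rules)) {
    y$planted_rules <- purrr::pmap(
      spec$planted_rules[, c("rule_id", "rule", "effect")],
      function(rule_id, rule, effect) {
        list(rule_id = rule_id, rule = format_rule(rule, spec$schema),
             effect = effect)
      })
  }
  yaml::write_yaml(y, path, precision = 15)
  invisible(path)
}

#' @rdname write_spec_yaml
#' @param schema The [covariate_schema()] the spec refers to.
#' @export
read_spec_yaml <- function(path, schema) {
  y <- yaml::read_yaml(path)
  marginals <- purrr::imap(y$marginals, function(m, v) {
    if (schema_kind(schema, v) == "categorical") unlist(m) else m
  })
  planted <- NULL
  if (!is.null(y$planted_rules)) {
    planted <- purrr::map_dfr(y$planted_rules, function(r) {
      tibble::tibble(rule_id = r$rule_id, effect = r$effect,
                     rule = list(parse_rule(r$rule, schema)))
    })
  }
  spec <- synthetic_spec(schema, y$n, marginals, baseline_logit = 0,
                         planted_rules = planted,
                         missingness = unlist(y$missingness),
                         seed = y$seed %||% 1L)
  spec$baseline_logit <- y$baseline_logit
  spec
}
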