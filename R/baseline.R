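#' Specify the multivariable logistic baseline model
#'
#' The comparison analysis: a complete-case maximum-likelihood logistic
#' regression with covariates entered in ordered blocks and optional
#' interactions, reported as coefficients, Wald standard errors and
#' p-values, odds ratios and 95% confidence intervals.
#'
#' @param blocks Ordered named list of character vectors: the covariates
#'   entering at each stage.
#' @param interactions List of length-2 character vectors; both members
#'   must appear as main effects.
#' @param references Named character vector of reference levels for
#'   categorical covariates (defaults to each variable's first schema
#'   level).
#' @return A `baseline_model_spec`.
#' @export
baseline_model_spec <- function(blocks, interactions = list(),
                                references = character()) {
  terms <- unlist(blocks, use.names = FALSE)
  if (anyDuplicated(terms)) {
    abort("a covariate appears in more than one block", class = "cohortrules_spec_error")
  }
  for (ia in interactions) {
    if (length(ia) != 2 || !all(ia %in% terms)) {
      abort("interaction members must appear as main effects",
            class = "cohortrules_spec_error")
    }
  }
  structure(list(blocks = blocks, terms = terms,
                 interactions = interactions, references = references),
            class = "baseline_model_spec")
}

#' The default baseline model for the TEDDY-like schema
#'
#' Blockwise entry — demographics (country, child sex, maternal age), then
#' maternal lifestyle during pregnancy (smoking, alcohol, employment), then
#' paternal participation, then maternal reactions to the child's risk
#' (risk-perception accuracy, anxiety score) — with the anxiety-by-
#' risk-perception interaction. Reference levels: United States,
#' non-smoker, no alcohol, risk underestimated.
#'
#' @return A [baseline_model_spec()].
#' @export
teddy_baseline_spec <- function() {
  baseline_model_spec(
    blocks = list(
      demographics = c("country", "child_sex", "maternal_age"),
      pregnancy = c("smoked", "alcohol_3rd_trimester", "worked_all_trimesters"),
      dad = "dad_participation",
      reactions = c("risk_perception", "anxiety_score")
    ),
    interactions = list(c("anxiety_score", "risk_perception")),
    references = c(country = "us", smoked = "no",
                   alcohol_3rd_trimester = "none",
                   worked_all_trimesters = "no",
                   dad_participation = "no",
                   risk_perception = "underestimate")
  )
}

baseline_formula <- function(spec, outcome) {
  rhs <- c(spec$terms,
           purrr::map_chr(spec$interactions, ~ paste(.x, collapse = ":")))
  if (length(rhs) == 0) rhs <- "1"  # intercept-only model
  stats::as.formula(paste(outcome, "~", paste(rhs, collapse = " + ")))
}

#' Fit the complete-case logistic baseline
#'
#' Restricts the cohort to records with no missing modeled covariate, fits
#' the blockwise logistic model by maximum likelihood, and reports Wald
#' inference per term, the likelihood-ratio model chi-square against the
#' intercept-only model, and classification accuracy at the 0.5 probability
#' cutoff. Divergent coefficients (separation) raise an explicit error
#' naming the offending term.
#'
#' @param cohort A cohort.
#' @param spec A [baseline_model_spec()] (default [teddy_baseline_spec()]).
#' @param conf_level Confidence level for the odds-ratio intervals.
#' @return A `baseline_fit`: `$coefficients` tibble (`term`, `estimate`,
#'   `se`, `statistic`, `p_value`, `odds_ratio`, `conf_low`, `conf_high`),
#'   `$model_chisq`, `$df`, `$p_model`, `$accuracy`, `$n_used`,
#'   `$n_dropped`, `$blocks` (cumulative log-likelihood per block),
#'   `$glm` (the underlying fit).
#' @export
fit_logistic_baseline <- function(cohort, spec = teddy_baseline_spec(),
                                  conf_level = 0.95) {
  schema <- cohort_schema(cohort)
  outcome <- schema_outcome(schema)
  unknown <- setdiff(spec$terms, schema$variable)
  if (length(unknown) > 0) {
    abort(paste0("model terms not in schema: ", paste(unknown, collapse = ", ")),
          class = "cohortrules_schema_error")
  }
  dat <- tibble::as_tibble(cohort)[, c(spec$terms, outcome), drop = FALSE]
  cc <- stats::complete.cases(dat)
  dat <- dat[cc, , drop = FALSE]

  for (v in spec$terms) {
    if (schema_kind(schema, v) == "categorical") {
      levs <- schema_levels(schema, v)
      ref <- if (v %in% names(spec$references)) spec$references[[v]] else levs[1]
      dat[[v]] <- factor(dat[[v]], levels = c(ref, setdiff(levs, ref)))
      dat[[v]] <- droplevels(dat[[v]])
    }
  }

  form <- baseline_formula(spec, outcome)
  n_params <- length(attr(stats::terms(form), "term.labels")) + 1
  if (nrow(dat) < n_params + 10) {
    abort(paste0("too few complete cases (", nrow(dat), ") for ",
                 n_params, " parameters"),
          class = "cohortrules_value_error")
  }
  saturated <- FALSE
  fit <- withCallingHandlers(
    glm(form, family = binomial(), data = dat),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        saturated <<- TRUE
      }
      invokeRestart("muffleWarning")
    }
  )
  cf <- coef(fit)
  # complete separation: the likelihood is unbounded and the deviance
  # collapses to zero while coefficients run away
  separated <- fit$deviance < 1e-6 && fit$df.residual > 0 && length(cf) > 1
  if (saturated || separated || !fit$converged || any(!is.finite(cf)) ||
      (length(cf) > 1 && any(abs(cf[-1]) > 15))) {
    bad <- if (length(cf) > 1) names(cf[-1])[which.max(abs(cf[-1]))] else names(cf)[1]
    abort(paste0("logistic fit did not converge (possible separation); ",
                 "largest coefficient: ", bad),
          class = "cohortrules_separation_error")
  }

  sm <- summary(fit)$coefficients
  z <- qnorm(1 - (1 - conf_level) / 2)
  coefficients <- tibble::tibble(
    term = rownames(sm),
    estimate = unname(sm[, 1]), se = unname(sm[, 2]),
    statistic = unname(sm[, 3]), p_value = unname(sm[, 4]),
    odds_ratio = exp(unname(sm[, 1])),
    conf_low = exp(unname(sm[, 1] - z * sm[, 2])),
    conf_high = exp(unname(sm[, 1] + z * sm[, 2]))
  )

  null_fit <- glm(stats::as.formula(paste(outcome, "~ 1")),
                  family = binomial(), data = dat)
  chisq <- as.numeric(2 * (logLik(fit) - logLik(null_fit)))
  df <- length(cf) - 1
  acc <- mean((predict(fit, type = "response") >= 0.5) == (dat[[outcome]] == 1))

  # staged entry: cumulative blocks, in-sample log-likelihood per stage
  blocks <- purrr::imap_dfr(seq_along(spec$blocks), function(i, .) {
    terms_i <- unlist(spec$blocks[seq_len(i)], use.names = FALSE)
    ias <- purrr::keep(spec$interactions, ~ all(.x %in% terms_i))
    rhs <- c(terms_i, purrr::map_chr(ias, ~ paste(.x, collapse = ":")))
    f <- stats::as.formula(paste(outcome, "~", paste(rhs, collapse = " + ")))
    bf <- suppressWarnings(glm(f, family = binomial(), data = dat))
    tibble::tibble(block = names(spec$blocks)[i],
                   n_terms = length(terms_i) + length(ias),
                   log_lik = as.numeric(logLik(bf)),
                   deviance = bf$deviance)
  })

  structure(list(coefficients = coefficients, model_chisq = chisq, df = df,
                 p_model = pchisq(chisq, df, lower.tail = FALSE),
                 accuracy = acc, n_used = nrow(dat),
                 n_dropped = sum(!cc), blocks = blocks,
                 spec = spec, glm = fit),
            class = "baseline_fit")
}

#' @export
print.baseline_fit <- function(x, ...) {
  cat("<baseline_fit> complete-case logistic regression, n = ", x$n_used,
      " (", x$n_dropped, " dropped), chi-square = ", sprintf("%.2f", x$model_chisq),
      " (", x$df, " df), accuracy = ", sprintf("%.1f%%", 100 * x$accuracy),
      "\n", sep = "")
  print(x$coefficients)
  invisible(x)
}

#' @method tidy baseline_fit
#' @export
tidy.baseline_fit <- function(x, ...) x$coefficients

#' @method glance baseline_fit
#' @export
glance.baseline_fit <- function(x, ...) {
  tibble::tibble(n_used = x$n_used, n_dropped = x$n_dropped,
                 model_chisq = x$model_chisq, df = x$df,
                 p_model = x$p_model, accuracy = x$accuracy)
}

#' Export a baseline fit as CSV
#' @param x A `baseline_fit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_baseline_csv <- function(x, path) {
  readr::write_csv(x$coefficients, path, progress = FALSE)
  invisible(path)
}

#' Which risk factors do the two analyses agree on?
#'
#' Tabulates, per modeled covariate, whether it is a significant regression
#' term (any associated coefficient with p below `alpha`, interactions
#' included) and/or appears inside at least one selected rule, flagging
#' factors found by only one analysis.
#'
#' @param fit A `baseline_fit`.
#' @param pruned A `pruned_rules` object (or a rule-set tibble).
#' @param alpha Significance threshold for regression terms.
#' @return A tibble (`covariate`, `in_regression`, `in_rules`, `flag`)
#'   with attribute `concordance` (|both| / |either|).
#' @export
compare_with_rules <- function(fit, pruned, alpha = 0.05) {
  rules_tbl <- if (inherits(pruned, "pruned_rules")) pruned$rules else pruned
  rule_feats <- unique(unlist(purrr::map(rules_tbl$rule,
                                         ~ .x$conditions$feature)))
  covs <- union(fit$spec$terms, rule_feats)
  cf <- fit$coefficients[fit$coefficients$term != "(Intercept)", ]
  out <- purrr::map_dfr(covs, function(v) {
    in_reg <- v %in% fit$spec$terms &&
      any(cf$p_value[grepl(v, cf$term, fixed = TRUE)] < alpha)
    in_rul <- v %in% rule_feats
    tibble::tibble(
      covariate = v, in_regression = in_reg, in_rules = in_rul,
      flag = dplyr::case_when(in_reg & in_rul ~ "both",
                              in_reg ~ "regression_only",
                              in_rul ~ "rule_only",
                              TRUE ~ "neither")
    )
  })
  either <- out$in_regression | out$in_rules
  attr(out, "concordance") <-
    if (any(either)) sum(out$in_regression & out$in_rules) / sum(either) else NA_real_
  out
}
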