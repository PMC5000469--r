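#' Prune a candidate rule pool to a sparse predictive set
#'
#' Stage 2 of the pipeline: builds the rule-endorsement indicator matrix,
#' drops constant and duplicate columns, selects the penalty by stratified
#' cross-validation ([select_lambda_cv()]) and refits at the chosen
#' penalty. Rules with nonzero coefficients are returned labeled
#' risk-increasing (positive coefficient) or risk-decreasing (negative).
#' An empty selection is a valid outcome (returned with a warning).
#'
#' @param pool A rule-pool tibble ([extract_rules()]) or list of rules.
#' @param cohort A cohort.
#' @param k,rule,nlambda,lambda_min_ratio Passed to [select_lambda_cv()].
#' @param tol Convergence tolerance of the final refit at the chosen
#'   penalty; the cross-validation fits use a looser 1e-4 (penalty
#'   selection by held-out deviance is insensitive to the last digits of
#'   the coefficients).
#' @param seed Seed for the fold assignment.
#' @return A `pruned_rules` object: `$rules` (tibble with `rule_id`,
#'   `text`, `coefficient`, `direction`, `rule`), `$intercept`,
#'   `$lambda_star`, `$cv` (the [select_lambda_cv()] result), `$dropped`
#'   (constant / duplicate column counts), `$n`.
#' @export
prune_rules <- function(pool, cohort, k = 10, rule = c("1se", "min"),
                        nlambda = 20, lambda_min_ratio = 0.05,
                        seed = 1L, tol = 1e-7) {
  rule <- match.arg(rule)
  pool_tbl <- if (is.data.frame(pool)) pool else rules_tibble(pool)
  if (nrow(pool_tbl) == 0) {
    abort("prune_rules needs a non-empty rule pool", class = "cohortrules_value_error")
  }
  schema <- cohort_schema(cohort)
  y <- cohort[[schema_outcome(schema)]]
  E <- endorsement_matrix(pool_tbl, cohort)
  colnames(E) <- pool_tbl$rule_id

  support <- colMeans(E)
  constant <- support == 0 | support == 1
  E2 <- E[, !constant, drop = FALSE]
  pool2 <- pool_tbl[!constant, , drop = FALSE]

  # duplicate endorsement patterns: keep the first rule of each pattern
  pat <- apply(E2, 2, paste, collapse = "")
  dup <- duplicated(pat)
  E3 <- E2[, !dup, drop = FALSE]
  pool3 <- pool2[!dup, , drop = FALSE]

  if (ncol(E3) == 0) {
    abort("no informative rule columns remain after dropping constants/duplicates",
          class = "cohortrules_value_error")
  }

  cv <- select_lambda_cv(E3, y, k = k, rule = rule, nlambda = nlambda,
                         lambda_min_ratio = lambda_min_ratio,
                         seed = seed, tol = 1e-4)
  fit <- fit_sparse_logistic(E3, y, cv$lambda_star, tol = tol)

  sel <- fit$beta != 0
  selected <- pool3[sel, , drop = FALSE]
  selected$coefficient <- unname(fit$beta[sel])
  selected$direction <- ifelse(selected$coefficient > 0, "increasing", "decreasing")
  selected <- selected[order(-abs(selected$coefficient)), ]

  if (nrow(selected) == 0) {
    warn("pruning selected no rules at the chosen penalty")
  }
  structure(list(rules = selected, intercept = fit$intercept,
                 lambda_star = cv$lambda_star, cv = cv, fit = fit,
                 dropped = c(constant = sum(constant), duplicate = sum(dup)),
                 q_in = nrow(pool_tbl), n = nrow(cohort)),
            class = "pruned_rules")
}

#' @export
print.pruned_rules <- function(x, ...) {
  cat("<pruned_rules> ", nrow(x$rules), " rules selected from ", x$q_in,
      " candidates (lambda* = ", format(x$lambda_star), ")\n", sep = "")
  if (nrow(x$rules) > 0) {
    for (i in seq_len(nrow(x$rules))) {
      cat(sprintf("  %+0.3f  [%s]  %s\n", x$rules$coefficient[i],
                  x$rules$direction[i], x$rules$text[i]))
    }
  }
  invisible(x)
}

#' @method tidy pruned_rules
#' @export
tidy.pruned_rules <- function(x, ...) {
  dplyr::select(x$rules, "rule_id", "text", "coefficient", "direction")
}

#' @method glance pruned_rules
#' @export
glance.pruned_rules <- function(x, ...) {
  tibble::tibble(n = x$n, q_candidates = x$q_in,
                 q_dropped_constant = unname(x$dropped["constant"]),
                 q_dropped_duplicate = unname(x$dropped["duplicate"]),
                 n_selected = nrow(x$rules),
                 lambda_star = x$lambda_star, cv_rule = x$cv$rule,
                 objective = x$fit$objective)
}

#' Serialize a pruned rule model to / from JSON
#'
#' Stores the selected rules in text form with their coefficients, the
#' intercept, the chosen penalty and the cross-validation table, so a
#' pruned model can be re-imported for profiling.
#'
#' @param x A `pruned_rules` object.
#' @param path File path.
#' @param schema A [covariate_schema()] (for re-parsing on read).
#' @return `write_pruned_model()` returns `path` invisibly.
#' @export
write_pruned_model <- function(x, path, schema = NULL) {
  obj <- list(
    intercept = x$intercept, lambda_star = x$lambda_star,
    cv_rule = x$cv$rule, n = x$n, q_in = x$q_in,
    rules = purrr::pmap(x$rules[, c("rule_id", "text", "coefficient", "direction")],
                        function(rule_id, text, coefficient, direction) {
                          list(rule_id = rule_id, rule = text,
                               coefficient = coefficient, direction = direction)
                        }),
    cv_table = x$cv$table[, c("lambda", "mean_deviance", "se", "n_selected")]
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_pruned_model
#' @export
read_pruned_model <- function(path, schema) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  rules <- purrr::map_dfr(obj$rules, function(r) {
    tibble::tibble(rule_id = r$rule_id, text = r$rule,
                   coefficient = r$coefficient, direction = r$direction,
                   rule = list(parse_rule(r$rule, schema)))
  })
  structure(list(rules = rules, intercept = obj$intercept,
                 lambda_star = obj$lambda_star,
                 cv = list(rule = obj$cv_rule,
                           table = purrr::map_dfr(obj$cv_table, tibble::as_tibble)),
                 dropped = c(constant = NA, duplicate = NA),
                 q_in = obj$q_in, n = obj$n),
            class = "pruned_rules")
}
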