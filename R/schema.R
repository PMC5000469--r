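#' Declare a covariate schema for a withdrawal cohort
#'
#' A schema names every covariate, its kind (categorical, continuous or
#' count), the admissible levels or range, and the binary outcome column.
#' All downstream stages (loading, synthesis, tree growth, rule evaluation,
#' regression) validate against it. The outcome is always coded 0/1 with
#' 1 = withdrawn.
#'
#' @param variables A data frame with columns `variable` (unique names),
#'   `kind` (one of `"categorical"`, `"continuous"`, `"count"`), `levels`
#'   (list column of character vectors; `NULL` for numeric kinds), and
#'   optionally `min`, `max` (numeric range for numeric kinds) and `derived`
#'   (logical; derived covariates, such as the per-record missing-data count,
#'   are recomputed rather than read from files).
#' @param outcome Name of the binary outcome column (default `"withdrawn"`).
#'
#' @return A `covariate_schema` object (a tibble of variable declarations
#'   with the outcome name attached).
#' @export
#' @examples
#' covariate_schema(
#'   tibble::tibble(
#'     variable = c("country", "maternal_age"),
#'     kind = c("categorical", "continuous"),
#'     levels = list(c("finland", "other"), NULL),
#'     min = c(NA, 15), max = c(NA, 50)
#'   )
#' )
covariate_schema <- function(variables, outcome = "withdrawn") {
  variables <- tibble::as_tibble(variables)
  required <- c("variable", "kind", "levels")
  missing_cols <- setdiff(required, names(variables))
  if (length(missing_cols) > 0) {
    abort(paste0("schema is missing column(s): ", paste(missing_cols, collapse = ", ")),
          class = "cohortrules_schema_error")
  }
  if (!"min" %in% names(variables)) variables$min <- NA_real_
  if (!"max" %in% names(variables)) variables$max <- NA_real_
  if (!"derived" %in% names(variables)) variables$derived <- FALSE
  variables$derived[is.na(variables$derived)] <- FALSE

  if (anyDuplicated(variables$variable)) {
    abort("schema variable names must be unique", class = "cohortrules_schema_error")
  }
  if (!all(variables$kind %in% c("categorical", "continuous", "count"))) {
    bad <- unique(variables$kind[!variables$kind %in% c("categorical", "continuous", "count")])
    abort(paste0("unknown variable kind(s): ", paste(bad, collapse = ", ")),
          class = "cohortrules_schema_error")
  }
  is_cat <- variables$kind == "categorical"
  n_lev <- vapply(variables$levels, length, integer(1))
  if (any(is_cat & n_lev < 2)) {
    abort(paste0("categorical variable(s) need >= 2 levels: ",
                 paste(variables$variable[is_cat & n_lev < 2], collapse = ", ")),
          class = "cohortrules_schema_error")
  }
  if (outcome %in% variables$variable) {
    abort("outcome must not also be declared as a covariate",
          class = "cohortrules_schema_error")
  }
  structure(
    variables[, c("variable", "kind", "levels", "min", "max", "derived")],
    outcome = outcome,
    class = c("covariate_schema", class(tibble::tibble()))
  )
}

#' @export
print.covariate_schema <- function(x, ...) {
  cat("<covariate_schema> ", nrow(x), " covariates, outcome = '",
      schema_outcome(x), "' (1 = withdrawn)\n", sep = "")
  NextMethod()
  invisible(x)
}

#' Outcome column name of a schema
#' @param schema A [covariate_schema()].
#' @return A string.
#' @export
schema_outcome <- function(schema) attr(schema, "outcome", exact = TRUE)

schema_kind <- function(schema, variable) {
  i <- match(variable, schema$variable)
  if (is.na(i)) {
    abort(paste0("unknown variable '", variable, "'"),
          class = "cohortrules_schema_error")
  }
  schema$kind[i]
}

schema_levels <- function(schema, variable) {
  schema$levels[[match(variable, schema$variable)]]
}

#' Schema of the TEDDY-like withdrawal cohort
#'
#' The covariate set used throughout the package's examples and simulations:
#' demographic variables (country, child sex, maternal age), maternal
#' lifestyle during pregnancy (smoking, third-trimester alcohol category,
#' employment), paternal study participation, maternal reactions to the
#' child's diabetes risk (risk-perception accuracy, state-anxiety score),
#' the count of negative life events, and the per-record count of missing
#' covariate cells (a derived covariate that rules may condition on).
#'
#' @return A [covariate_schema()].
#' @export
teddy_schema <- function() {
  covariate_schema(tibble::tibble(
    variable = c("country", "child_sex", "maternal_age", "smoked",
                 "alcohol_3rd_trimester", "worked_all_trimesters",
                 "dad_participation", "risk_perception", "anxiety_score",
                 "negative_life_events", "missing_count"),
    kind = c("categorical", "categorical", "continuous", "categorical",
             "categorical", "categorical", "categorical", "categorical",
             "continuous", "count", "count"),
    levels = list(
      c("finland", "germany", "sweden", "us"),
      c("male", "female"),
      NULL,
      c("no", "yes"),
      c("none", "monthly_1_2", "monthly_3_plus"),
      c("no", "yes"),
      c("no", "yes"),
      c("underestimate", "accurate"),
      NULL, NULL, NULL
    ),
    min = c(NA, NA, 15, NA, NA, NA, NA, NA, 20, 0, 0),
    max = c(NA, NA, 50, NA, NA, NA, NA, NA, 80, Inf, Inf),
    derived = c(rep(FALSE, 10), TRUE)
  ))
}

#' Read / write a schema as YAML
#'
#' @param path File path.
#' @return `read_schema_yaml()` returns a [covariate_schema()];
#'   `write_schema_yaml()` returns `path` invisibly.
#' @export
read_schema_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  vars <- purrr::map_dfr(y$variables, function(v) {
    tibble::tibble(
      variable = v$name, kind = v$kind,
      levels = list(if (is.null(v$levels)) NULL else as.character(v$levels)),
      min = v$min %||% NA_real_, max = v$max %||% NA_real_,
      derived = isTRUE(v$derived)
    )
  })
  covariate_schema(vars, outcome = y$outcome %||% "withdrawn")
}

#' @rdname read_schema_yaml
#' @param schema A [covariate_schema()].
#' @export
write_schema_yaml <- function(schema, path) {
  y <- list(
    outcome = schema_outcome(schema),
    variables = purrr::pmap(schema, function(variable, kind, levels, min, max, derived) {
      out <- list(name = variable, kind = kind)
      if (!is.null(levels)) out$levels <- as.list(levels)
      if (!is.na(min)) out$min <- min
      if (!is.na(max) && is.finite(max)) out$max <- max
      if (derived) out$derived <- TRUE
      out
    })
  )
  yaml::write_yaml(y, path)
  invisible(path)
}
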