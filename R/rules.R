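#' Rules: conjunctions of covariate conditions
#'
#' A rule is a conjunction (logical AND) of conditions on covariates:
#' threshold conditions for numeric/count variables (`<`, `<=`, `>`, `>=`)
#' and level-membership conditions for categorical ones. A participant
#' *endorses* a rule when every condition holds; a condition evaluated on a
#' missing value is false, so missingness never counts as endorsement.
#'
#' `rule_condition()` builds one condition; `rule()` assembles conditions
#' into a rule; `parse_rule()` reads the human-readable text form, e.g.
#' `"maternal_age < 27.5 AND country != finland"` or
#' `"alcohol_3rd_trimester in {monthly_1_2, monthly_3_plus}"`.
#'
#' @param feature Covariate name.
#' @param op One of `"<"`, `"<="`, `">"`, `">="` (numeric/count) or `"in"`
#'   (categorical level membership).
#' @param value A finite numeric threshold, or a character vector of levels.
#' @return `rule_condition()`: a one-row tibble. `rule()`: a `rule` object.
#' @export
rule_condition <- function(feature, op, value) {
  if (op %in% c("<", "<=", ">", ">=")) {
    value <- as.numeric(value)
    if (length(value) != 1 || !is.finite(value)) {
      abort("numeric condition needs a single finite threshold",
            class = "cohortrules_rule_error")
    }
  } else if (op == "in") {
    value <- as.character(value)
    if (length(value) == 0) {
      abort("categorical condition needs a non-empty level set",
            class = "cohortrules_rule_error")
    }
  } else {
    abort(paste0("unknown comparator '", op, "'"), class = "cohortrules_rule_error")
  }
  tibble::tibble(feature = feature, op = op, value = list(value))
}

#' @rdname rule_condition
#' @param ... Conditions built with [rule_condition()] (or a single data
#'   frame of them).
#' @param provenance Optional `(tree_id, node_id)` pair recording where an
#'   extracted rule came from.
#' @export
rule <- function(..., provenance = NULL) {
  parts <- list(...)
  conditions <- if (length(parts) == 1 && is.data.frame(parts[[1]])) {
    tibble::as_tibble(parts[[1]])
  } else {
    dplyr::bind_rows(parts)
  }
  if (nrow(conditions) == 0) {
    abort("a rule needs at least one condition", class = "cohortrules_rule_error")
  }
  structure(list(conditions = conditions, provenance = provenance),
            class = "rule")
}

#' @export
print.rule <- function(x, ...) {
  cat("<rule> ", format_rule(x), "\n", sep = "")
  invisible(x)
}

#' @export
format.rule <- function(x, ...) format_rule(x)

#' Text form of a rule
#'
#' Single-level membership prints as `= level`; the complement of a single
#' level (given the schema) prints as `!= level`; other sets print as
#' `in {a, b}`.
#'
#' @param x A rule.
#' @param schema Optional [covariate_schema()] used to recognise
#'   complement-of-one-level sets.
#' @return A string.
#' @export
format_rule <- function(x, schema = NULL) {
  conds <- x$conditions
  txt <- purrr::map_chr(seq_len(nrow(conds)), function(i) {
    v <- conds$value[[i]]
    if (conds$op[i] == "in") {
      if (length(v) == 1) {
        sprintf("%s = %s", conds$feature[i], v)
      } else if (!is.null(schema)) {
        levs <- schema_levels(schema, conds$feature[i])
        out_set <- setdiff(levs, v)
        if (length(out_set) == 1 && setequal(v, setdiff(levs, out_set))) {
          sprintf("%s != %s", conds$feature[i], out_set)
        } else {
          sprintf("%s in {%s}", conds$feature[i], paste(v, collapse = ", "))
        }
      } else {
        sprintf("%s in {%s}", conds$feature[i], paste(v, collapse = ", "))
      }
    } else {
      sprintf("%s %s %s", conds$feature[i], conds$op[i],
              format(v, digits = 10, trim = TRUE))
    }
  })
  paste(txt, collapse = " AND ")
}

#' @rdname rule_condition
#' @param text Text form of a rule.
#' @param schema A [covariate_schema()]; needed to type thresholds and to
#'   expand `!=` into level sets.
#' @export
parse_rule <- function(text, schema) {
  parts <- strsplit(text, "\\s+AND\\s+")[[1]]
  conds <- purrr::map_dfr(parts, function(p) {
    p <- trimws(p)
    m <- regmatches(p, regexec("^([A-Za-z0-9_.]+)\\s*(<=|>=|!=|<|>|=|in)\\s*(.+)$", p))[[1]]
    if (length(m) == 0) {
      abort(paste0("cannot parse condition: '", p, "'"), class = "cohortrules_rule_error")
    }
    feature <- m[2]; op <- m[3]; rhs <- trimws(m[4])
    kind <- schema_kind(schema, feature)
    if (kind == "categorical") {
      levs <- schema_levels(schema, feature)
      if (op == "in") {
        vals <- trimws(strsplit(gsub("[{}]", "", rhs), ",")[[1]])
      } else if (op == "=") {
        vals <- rhs
      } else if (op == "!=") {
        vals <- setdiff(levs, rhs)
      } else {
        abort(paste0("comparator '", op, "' invalid for categorical '", feature, "'"),
              class = "cohortrules_rule_error")
      }
      bad <- setdiff(if (op == "!=") rhs else vals, levs)
      if (length(bad) > 0) {
        abort(paste0("unknown level(s) for '", feature, "': ", paste(bad, collapse = ", ")),
              class = "cohortrules_rule_error")
      }
      rule_condition(feature, "in", vals)
    } else {
      if (!op %in% c("<", "<=", ">", ">=")) {
        abort(paste0("comparator '", op, "' invalid for numeric '", feature, "'"),
              class = "cohortrules_rule_error")
      }
      rule_condition(feature, op, as.numeric(rhs))
    }
  })
  rule(conds)
}

#' Simplify a rule to at most one interval / level set per feature
#'
#' Merges repeated numeric conditions into the tightest interval (e.g.
#' `age < 27.5 AND age < 25` becomes `age < 25`) and intersects categorical
#' level sets. A rule whose merged conditions can never hold (empty interval
#' or empty level set) is flagged infeasible and endorses no record.
#'
#' @param x A rule.
#' @param schema A [covariate_schema()] (fixes the canonical feature order).
#' @return A simplified rule; infeasible rules carry attribute
#'   `infeasible = TRUE`.
#' @export
simplify_rule <- function(x, schema) {
  conds <- x$conditions
  feats <- intersect(schema$variable, unique(conds$feature))
  extra <- setdiff(unique(conds$feature), schema$variable)
  if (length(extra) > 0) {
    abort(paste0("rule references unknown feature(s): ", paste(extra, collapse = ", ")),
          class = "cohortrules_schema_error")
  }
  infeasible <- FALSE
  out <- purrr::map_dfr(feats, function(f) {
    cf <- conds[conds$feature == f, ]
    if (cf$op[1] == "in") {
      set <- Reduce(intersect, cf$value)
      levs <- schema_levels(schema, f)
      set <- levs[levs %in% set]
      if (length(set) == 0) {
        infeasible <<- TRUE
        return(rule_condition(f, "in", "..impossible.."))
      }
      if (setequal(set, levs)) return(NULL)  # vacuous
      rule_condition(f, "in", set)
    } else {
      lo <- NULL; up <- NULL  # each: list(val, strict)
      for (i in seq_len(nrow(cf))) {
        v <- cf$value[[i]]
        switch(cf$op[i],
          "<"  = { up <- tighter_upper(up, list(val = v, strict = TRUE)) },
          "<=" = { up <- tighter_upper(up, list(val = v, strict = FALSE)) },
          ">"  = { lo <- tighter_lower(lo, list(val = v, strict = TRUE)) },
          ">=" = { lo <- tighter_lower(lo, list(val = v, strict = FALSE)) })
      }
      if (!is.null(lo) && !is.null(up)) {
        if (lo$val > up$val ||
            (lo$val == up$val && (lo$strict || up$strict))) infeasible <<- TRUE
      }
      dplyr::bind_rows(
        if (!is.null(lo)) rule_condition(f, if (lo$strict) ">" else ">=", lo$val),
        if (!is.null(up)) rule_condition(f, if (up$strict) "<" else "<=", up$val)
      )
    }
  })
  r <- rule(out, provenance = x$provenance)
  attr(r, "infeasible") <- infeasible
  r
}

tighter_upper <- function(cur, cand) {
  if (is.null(cur)) return(cand)
  if (cand$val < cur$val || (cand$val == cur$val && cand$strict)) cand else cur
}

tighter_lower <- function(cur, cand) {
  if (is.null(cur)) return(cand)
  if (cand$val > cur$val || (cand$val == cur$val && cand$strict)) cand else cur
}

#' Evaluate rule endorsement on a cohort
#'
#' `endorse()` returns the logical endorsement vector of one rule;
#' `endorsement_matrix()` evaluates a whole rule set into the n-by-q binary
#' indicator matrix used as the design matrix of the pruning stage. A
#' condition on a missing value is false.
#'
#' @param x A rule.
#' @param data A cohort (or any data frame with the rule's features).
#' @return `endorse()`: a logical vector of length `nrow(data)`.
#' @export
endorse <- function(x, data) {
  if (isTRUE(attr(x, "infeasible"))) return(rep(FALSE, nrow(data)))
  conds <- x$conditions
  extra <- setdiff(unique(conds$feature), names(data))
  if (length(extra) > 0) {
    abort(paste0("rule references unknown feature(s): ", paste(extra, collapse = ", ")),
          class = "cohortrules_schema_error")
  }
  out <- rep(TRUE, nrow(data))
  for (i in seq_len(nrow(conds))) {
    col <- data[[conds$feature[i]]]
    v <- conds$value[[i]]
    ok <- switch(conds$op[i],
                 "<"  = col <  v,
                 "<=" = col <= v,
                 ">"  = col >  v,
                 ">=" = col >= v,
                 "in" = col %in% v)
    ok[is.na(ok)] <- FALSE
    out <- out & ok
  }
  out
}

#' @rdname endorse
#' @param rules A rule set: a list of rules, or a tibble with a `rule` list
#'   column (as returned by [extract_rules()] or [teddy_rules()]).
#' @param cohort A cohort.
#' @return `endorsement_matrix()`: an integer n-by-q matrix with one column
#'   per rule (named by rule id).
#' @export
endorsement_matrix <- function(rules, cohort) {
  rules <- as_rule_list(rules)
  n <- nrow(cohort)
  if (length(rules) == 0) {
    return(matrix(integer(0), nrow = n, ncol = 0))
  }
  cols <- purrr::map(rules, ~ as.integer(endorse(.x, cohort)))
  m <- do.call(cbind, cols)
  colnames(m) <- names(rules) %||% paste0("rule_", seq_along(rules))
  m
}

as_rule_list <- function(rules) {
  if (inherits(rules, "rule")) return(list(rules))
  if (is.data.frame(rules)) {
    rl <- rules$rule
    names(rl) <- rules$rule_id %||% paste0("rule_", seq_len(nrow(rules)))
    return(rl)
  }
  if (is.list(rules)) {
    if (length(rules) > 0 && is.null(names(rules))) {
      names(rules) <- paste0("rule_", seq_along(rules))
    }
    return(rules)
  }
  abort("cannot interpret `rules` as a rule set", class = "cohortrules_rule_error")
}

#' Tabulate a rule set
#'
#' @param rules A list of rules.
#' @param schema Optional schema, for `!=` sugar in the text form.
#' @return A tibble with columns `rule_id`, `text`, `n_conditions`, `rule`.
#' @export
rules_tibble <- function(rules, schema = NULL) {
  rules <- as_rule_list(rules)
  tibble::tibble(
    rule_id = names(rules),
    text = purrr::map_chr(rules, format_rule, schema = schema),
    n_conditions = purrr::map_int(rules, ~ nrow(.x$conditions)),
    rule = unname(rules)
  )
}

#' Jaccard similarity of two endorsement patterns
#'
#' |A intersect B| / |A union B| over the endorsing record sets; 1 when both
#' sets are empty (identical patterns).
#'
#' @param e1,e2 Logical or 0/1 endorsement vectors of equal length.
#' @return A number in \[0, 1\].
#' @export
endorsement_jaccard <- function(e1, e2) {
  e1 <- as.logical(e1); e2 <- as.logical(e2)
  u <- sum(e1 | e2)
  if (u == 0) return(1)
  sum(e1 & e2) / u
}

#' The eight packaged risk-predictive rules
#'
#' The eight withdrawal rules reported for the TEDDY first-year cohort,
#' shipped as a plain-text fixture: four risk-increasing (young non-Finnish
#' mothers; smoking with inaccurate risk perception and high anxiety; high
#' anxiety without paternal participation; young mothers with inaccurate
#' risk perception and little alcohol use) and four risk-decreasing rules
#' (employment without smoking; non-Finnish moderate drinkers with few
#' negative life events; non-smokers with low anxiety and complete data;
#' older non-smoking mothers with complete data).
#'
#' @param schema A [covariate_schema()] (default [teddy_schema()]).
#' @return A tibble with columns `rule_id`, `direction`
#'   (`"increasing"`/`"decreasing"`), `text` and `rule`.
#' @export
teddy_rules <- function(schema = teddy_schema()) {
  path <- system.file("extdata", "teddy_rules.tsv", package = "cohortrules")
  read_rules(path, schema)
}

#' Read / write rule sets as delimited text
#'
#' The on-disk form is a TSV with columns `rule_id`, `direction` (optional)
#' and `rule` (the text form understood by [parse_rule()]).
#'
#' @param path File path.
#' @param schema A [covariate_schema()].
#' @return `read_rules()`: a tibble with `rule_id`, `direction` (if
#'   present), `text`, `rule`.
#' @export
read_rules <- function(path, schema) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  out <- tibble::tibble(
    rule_id = raw$rule_id,
    text = raw$rule,
    rule = purrr::map(raw$rule, parse_rule, schema = schema)
  )
  if ("direction" %in% names(raw)) {
    out <- tibble::add_column(out, direction = raw$direction, .after = "rule_id")
  }
  out
}

#' @rdname read_rules
#' @param rules A rule-set tibble (with `rule_id`, `rule` and optionally
#'   `direction` columns) or a list of rules.
#' @export
write_rules <- function(rules, path, schema = NULL) {
  if (!is.data.frame(rules)) rules <- rules_tibble(rules, schema)
  out <- tibble::tibble(
    rule_id = rules$rule_id,
    rule = purrr::map_chr(rules$rule, format_rule, schema = schema)
  )
  if ("direction" %in% names(rules)) {
    out <- tibble::add_column(out, direction = rules$direction, .after = "rule_id")
  }
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
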