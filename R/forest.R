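#' Grow a bootstrapped, feature-subsampled forest of rule-generating trees
#'
#' Each tree is grown on an independent bootstrap resample of the cohort
#' (with replacement, at full cohort size) with its leaf limit drawn
#' uniformly from `2:max_leaves` and a fresh `mtry`-feature subsample at
#' every split. Per-tree seeds are derived from `params$seed`, so the
#' forest is reproducible regardless of evaluation order.
#'
#' @param cohort A cohort.
#' @param params A [forest_params()].
#' @return A `rule_forest`: list of `decision_tree` objects with the schema
#'   attached.
#' @export
grow_forest <- function(cohort, params = forest_params()) {
  if (nrow(cohort) == 0) {
    abort("cannot grow a forest on an empty cohort", class = "cohortrules_value_error")
  }
  schema <- cohort_schema(cohort)
  finfo <- feature_frame(cohort, schema)
  y <- cohort[[schema_outcome(schema)]]
  n <- nrow(cohort)

  trees <- purrr::map(seq_len(params$n_trees), function(t) {
    with_seed(derive_seed(params$seed, paste0("tree_", t)), {
      rows <- sample.int(n, n, replace = TRUE)
      leaf_limit <- if (params$max_leaves > 2) {
        sample(2:params$max_leaves, 1)
      } else 2L
      nodes <- grow_tree_impl(finfo, y, rows, params, leaf_limit)
      structure(list(nodes = nodes, schema = schema, n = n, tree_id = t),
                class = "decision_tree")
    })
  })
  structure(list(trees = trees, schema = schema, params = params),
            class = "rule_forest")
}

#' @export
print.rule_forest <- function(x, ...) {
  cat("<rule_forest> ", length(x$trees), " trees, ",
      sum(purrr::map_int(x$trees, ~ length(.x$nodes))), " nodes total\n", sep = "")
  invisible(x)
}

# All path rules of one tree: one rule per non-root node (or per leaf),
# the conjunction of edge conditions from the root, simplified.
tree_rules <- function(tree, mode = "all") {
  schema <- tree$schema
  out <- list()
  walk <- function(id, conds) {
    nd <- tree$nodes[[id]]
    if (!is.na(nd$parent) && (mode == "all" || nd$is_leaf)) {
      r <- rule(dplyr::bind_rows(conds),
                provenance = c(tree_id = tree$tree_id %||% 1L, node_id = id))
      out[[length(out) + 1]] <<- simplify_rule(r, schema)
    }
    if (!nd$is_leaf) {
      for (side in 1:2) {
        walk(nd$children[side],
             c(conds, list(path_condition(nd, side, schema))))
      }
    }
  }
  if (length(tree$nodes) > 1) walk(1L, list())
  out
}

#' Extract the candidate rule pool from a forest
#'
#' Every non-root node of every tree contributes the conjunction of
#' conditions on its root path (`mode = "all"`, the rule-ensemble default;
#' `mode = "leaves"` restricts to leaf nodes). Rules are simplified to one
#' interval / level set per feature and deduplicated across the forest by
#' their canonical text form. Single-leaf trees contribute nothing.
#'
#' @param forest A `rule_forest` (or a list of `decision_tree`s).
#' @param mode `"all"` or `"leaves"`; default taken from the forest's
#'   params.
#' @return A rule-pool tibble: `rule_id`, `text`, `n_conditions`, `rule`,
#'   with the pool size `q` as attribute.
#' @export
extract_rules <- function(forest, mode = NULL) {
  trees <- if (inherits(forest, "rule_forest")) forest$trees else forest
  if (length(trees) == 0) {
    abort("extract_rules needs a non-empty forest", class = "cohortrules_value_error")
  }
  mode <- mode %||%
    (if (inherits(forest, "rule_forest")) forest$params$rule_nodes else "all")
  schema <- trees[[1]]$schema
  all_rules <- purrr::flatten(purrr::map(trees, tree_rules, mode = mode))
  if (length(all_rules) == 0) {
    pool <- tibble::tibble(rule_id = character(), text = character(),
                           n_conditions = integer(), rule = list())
    attr(pool, "q") <- 0L
    return(pool)
  }
  texts <- purrr::map_chr(all_rules, format_rule)
  keep <- !duplicated(texts)
  rules <- all_rules[keep]
  pool <- tibble::tibble(
    rule_id = sprintf("r%04d", seq_along(rules)),
    text = texts[keep],
    n_conditions = purrr::map_int(rules, ~ nrow(.x$conditions)),
    rule = rules
  )
  attr(pool, "q") <- nrow(pool)
  pool
}
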