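#' Forest hyper-parameters for rule generation
#'
#' @param n_trees Number of trees (each grown on its own bootstrap
#'   resample).
#' @param max_leaves Upper bound on tree size; each tree's leaf limit is
#'   drawn uniformly from `2:max_leaves`, the varied-tree-size convention of
#'   rule-ensemble learning.
#' @param min_leaf Minimum number of records per leaf.
#' @param mtry Number of features considered per split; default
#'   `ceiling(sqrt(p))`, the classic random-forest rule.
#' @param seed Integer seed; forests are fully reproducible from it.
#' @param rule_nodes `"all"` extracts a rule from every non-root node
#'   (rule-ensemble practice, the default); `"leaves"` from leaf nodes only.
#' @return A `forest_params` list.
#' @export
forest_params <- function(n_trees = 100, max_leaves = 8, min_leaf = 10,
                          mtry = NULL, seed = 1L,
                          rule_nodes = c("all", "leaves")) {
  if (n_trees < 1) abort("n_trees must be >= 1", class = "cohortrules_spec_error")
  if (min_leaf < 1) abort("min_leaf must be >= 1", class = "cohortrules_spec_error")
  if (max_leaves < 2) abort("max_leaves must be >= 2", class = "cohortrules_spec_error")
  list(n_trees = as.integer(n_trees), max_leaves = as.integer(max_leaves),
       min_leaf = as.integer(min_leaf), mtry = mtry, seed = as.integer(seed),
       rule_nodes = match.arg(rule_nodes))
}

# Column-wise numeric / categorical-code matrices for fast split search.
feature_frame <- function(cohort, schema = cohort_schema(cohort)) {
  feats <- schema$variable
  info <- purrr::map(seq_along(feats), function(i) {
    v <- feats[i]
    if (schema$kind[i] == "categorical") {
      levs <- schema$levels[[i]]
      list(name = v, type = "cat", levels = levs,
           codes = match(cohort[[v]], levs))
    } else {
      list(name = v, type = "num", levels = NULL,
           values = as.numeric(cohort[[v]]))
    }
  })
  names(info) <- feats
  info
}

best_split_for_feature <- function(fi, rows, y, min_leaf) {
  if (fi$type == "num") {
    xv <- fi$values[rows]
    ok <- !is.na(xv)
    if (sum(ok) < 2 * min_leaf) return(NULL)
    res <- .best_split_num_cpp(xv[ok], y[rows][ok], min_leaf)
    if (!isTRUE(res$found)) return(NULL)
    list(feature = fi$name, type = "num", threshold = res$threshold,
         level = NULL, gain = res$gain)
  } else {
    codes <- fi$codes[rows]
    ok <- !is.na(codes)
    nc <- sum(ok)
    if (nc < 2 * min_leaf) return(NULL)
    yy <- y[rows][ok]
    cc <- codes[ok]
    L <- length(fi$levels)
    n_l <- tabulate(cc, nbins = L)
    pos_l <- tabulate(cc[yy == 1], nbins = L)
    tot_pos <- sum(pos_l)
    g_parent <- 2 * tot_pos * (nc - tot_pos) / nc
    best <- NULL
    for (l in seq_len(L)) {  # one-level-vs-rest splits only
      nl <- n_l[l]; nr <- nc - nl
      if (nl < min_leaf || nr < min_leaf) next
      pl <- pos_l[l]; pr <- tot_pos - pl
      gain <- g_parent - 2 * pl * (nl - pl) / nl - 2 * pr * (nr - pr) / nr
      if (is.null(best) || gain > best$gain + 1e-12) {
        best <- list(feature = fi$name, type = "cat", threshold = NULL,
                     level = fi$levels[l], gain = gain)
      }
    }
    best
  }
}

# Best split at a node over a freshly drawn feature subset; features are
# scanned in schema order so equal-gain ties resolve to the lowest feature
# index (and, inside a feature, the smallest threshold / level index).
best_split_node <- function(rows, y, finfo, min_leaf, mtry) {
  if (length(rows) < 2 * min_leaf) return(NULL)
  pos <- sum(y[rows])
  if (pos == 0 || pos == length(rows)) return(NULL)  # pure node
  p <- length(finfo)
  take <- sort(sample.int(p, min(mtry, p)))
  best <- NULL
  for (k in take) {
    cand <- best_split_for_feature(finfo[[k]], rows, y, min_leaf)
    if (!is.null(cand) && cand$gain > 1e-12 &&
        (is.null(best) || cand$gain > best$gain + 1e-12)) {
      best <- cand
    }
  }
  best
}

split_membership <- function(split, finfo, rows) {
  fi <- finfo[[split$feature]]
  if (split$type == "num") {
    cond <- fi$values[rows] < split$threshold
  } else {
    cond <- fi$codes[rows] == match(split$level, fi$levels)
  }
  cond  # NA where the feature is missing
}

grow_tree_impl <- function(finfo, y, rows, params, leaf_limit) {
  mtry <- params$mtry %||% ceiling(sqrt(length(finfo)))
  nodes <- list()
  new_node <- function(parent, depth, rows) {
    id <- length(nodes) + 1L
    nodes[[id]] <<- list(id = id, parent = parent, depth = depth,
                         n = length(rows), n_pos = sum(y[rows]),
                         pred = if (length(rows)) mean(y[rows]) else NA_real_,
                         is_leaf = TRUE, split = NULL,
                         children = NULL, missing_to = NA_integer_)
    id
  }
  root <- new_node(NA_integer_, 0L, rows)
  frontier <- list(list(id = root, rows = rows,
                        best = best_split_node(rows, y, finfo,
                                               params$min_leaf, mtry)))
  n_leaves <- 1L
  while (n_leaves < leaf_limit) {
    gains <- purrr::map_dbl(frontier, ~ if (is.null(.x$best)) -Inf else .x$best$gain)
    if (all(gains == -Inf)) break
    k <- which.max(gains)  # ties resolve to the earliest-created node
    ent <- frontier[[k]]
    frontier <- frontier[-k]
    split <- ent$best
    cond <- split_membership(split, finfo, ent$rows)
    left_rows <- ent$rows[which(cond)]
    right_rows <- ent$rows[which(!cond)]
    miss_rows <- ent$rows[is.na(cond)]
    # growth-time statistics route missing records with the majority child
    go_left <- length(left_rows) >= length(right_rows)
    if (go_left) left_rows <- c(left_rows, miss_rows) else right_rows <- c(right_rows, miss_rows)
    lid <- new_node(ent$id, nodes[[ent$id]]$depth + 1L, left_rows)
    rid <- new_node(ent$id, nodes[[ent$id]]$depth + 1L, right_rows)
    nodes[[ent$id]]$is_leaf <- FALSE
    nodes[[ent$id]]$split <- split
    nodes[[ent$id]]$children <- c(lid, rid)
    nodes[[ent$id]]$missing_to <- if (go_left) lid else rid
    frontier <- c(frontier,
                  list(list(id = lid, rows = left_rows,
                            best = best_split_node(left_rows, y, finfo,
                                                   params$min_leaf, mtry)),
                       list(id = rid, rows = right_rows,
                            best = best_split_node(right_rows, y, finfo,
                                                   params$min_leaf, mtry))))
    n_leaves <- n_leaves + 1L
  }
  nodes
}

#' Grow one recursive-partitioning tree
#'
#' Greedy binary partitioning of the cohort maximizing the Gini impurity
#' decrease, grown best-first up to `leaf_limit` leaves (the frontier leaf
#' with the largest gain splits next). Numeric thresholds sit at midpoints
#' of adjacent observed values; categorical splits are one-level-vs-rest.
#' Records missing the split feature are excluded from that split's
#' evaluation and follow the majority child for growth-time statistics.
#'
#' @param cohort A cohort.
#' @param params A [forest_params()].
#' @param leaf_limit Maximum number of leaves for this tree (default
#'   `params$max_leaves`).
#' @param seed Optional seed for the per-split feature subsample; when
#'   `NULL` the current RNG state is used (as [grow_forest()] does).
#' @return A `decision_tree` object.
#' @export
grow_tree <- function(cohort, params = forest_params(), leaf_limit = NULL,
                      seed = NULL) {
  if (nrow(cohort) == 0) {
    abort("cannot grow a tree on an empty cohort", class = "cohortrules_value_error")
  }
  schema <- cohort_schema(cohort)
  finfo <- feature_frame(cohort, schema)
  y <- cohort[[schema_outcome(schema)]]
  leaf_limit <- leaf_limit %||% params$max_leaves
  grow <- function() grow_tree_impl(finfo, y, seq_len(nrow(cohort)), params, leaf_limit)
  nodes <- if (is.null(seed)) grow() else with_seed(seed, grow())
  structure(list(nodes = nodes, schema = schema, n = nrow(cohort)),
            class = "decision_tree")
}

#' @export
print.decision_tree <- function(x, ...) {
  cat("<decision_tree> ", length(x$nodes), " nodes, ",
      sum(purrr::map_lgl(x$nodes, "is_leaf")), " leaves\n", sep = "")
  for (nd in x$nodes) {
    pad <- strrep("  ", nd$depth)
    lab <- if (is.na(nd$parent)) "root" else {
      par <- x$nodes[[nd$parent]]
      cond <- path_condition(par, which(par$children == nd$id), x$schema)
      format_rule(rule(cond), x$schema)
    }
    cat(pad, lab, "  [n=", nd$n, ", rate=", sprintf("%.3f", nd$pred), "]",
        if (nd$is_leaf) "  *" else "", "\n", sep = "")
  }
  invisible(x)
}

n_leaves <- function(tree) sum(purrr::map_lgl(tree$nodes, "is_leaf"))

# Condition carried by edge `side` (1 = condition-true child, 2 = false
# child) out of an internal node.
path_condition <- function(node, side, schema) {
  s <- node$split
  if (s$type == "num") {
    if (side == 1) rule_condition(s$feature, "<", s$threshold)
    else rule_condition(s$feature, ">=", s$threshold)
  } else {
    levs <- schema_levels(schema, s$feature)
    if (side == 1) rule_condition(s$feature, "in", s$level)
    else rule_condition(s$feature, "in", setdiff(levs, s$level))
  }
}

#' Node membership of records in a tree
#'
#' Returns the n-by-#nodes logical matrix of which records belong to which
#' node. Under `missing = "strict"` a record missing a split feature leaves
#' the routing at that node (matching rule-endorsement semantics, where a
#' condition on a missing value is false); under `"majority"` it follows
#' the majority child, as during growth.
#'
#' @param tree A `decision_tree`.
#' @param data A cohort or data frame with the tree's features.
#' @param missing `"strict"` or `"majority"`.
#' @return A logical matrix, columns in node-id order.
#' @export
node_membership <- function(tree, data, missing = c("strict", "majority")) {
  missing <- match.arg(missing)
  n <- nrow(data)
  M <- matrix(FALSE, nrow = n, ncol = length(tree$nodes))
  M[, 1] <- TRUE
  for (nd in tree$nodes) {
    if (nd$is_leaf) next
    s <- nd$split
    x <- data[[s$feature]]
    cond <- if (s$type == "num") x < s$threshold else x == s$level
    here <- M[, nd$id]
    left <- here & !is.na(cond) & cond
    right <- here & !is.na(cond) & !cond
    if (missing == "majority") {
      miss <- here & is.na(cond)
      if (nd$missing_to == nd$children[1]) left <- left | miss else right <- right | miss
    }
    M[, nd$children[1]] <- left
    M[, nd$children[2]] <- right
  }
  M
}

#' @export
predict.decision_tree <- function(object, newdata,
                                  missing = c("majority", "strict"), ...) {
  missing <- match.arg(missing)
  M <- node_membership(object, newdata, missing = missing)
  preds <- rep(NA_real_, nrow(newdata))
  for (nd in object$nodes) {
    if (nd$is_leaf) preds[M[, nd$id]] <- nd$pred
  }
  preds
}
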