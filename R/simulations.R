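#' Draw random candidate rules over a schema
#'
#' Samples simple one- or two-condition rules (quantile thresholds for
#' numeric covariates, single levels for categorical ones) from a cohort's
#' observed covariates. Used to build noise rule pools that are independent
#' of the outcome by construction when the generating model plants no
#' effects.
#'
#' @param schema A [covariate_schema()].
#' @param cohort A cohort supplying the threshold quantiles.
#' @param q Number of rules.
#' @param seed Integer seed.
#' @param max_conditions 1 or 2 conditions per rule (drawn uniformly).
#' @return A rule-set tibble (`rule_id`, `text`, `rule`).
#' @export
sample_rules <- function(schema, cohort, q, seed = 1L, max_conditions = 2) {
  draw_condition <- function() {
    repeat {
      i <- sample(nrow(schema), 1)
      v <- schema$variable[i]
      if (schema$kind[i] == "categorical") {
        return(rule_condition(v, "in", sample(schema$levels[[i]], 1)))
      }
      x <- cohort[[v]]
      x <- x[!is.na(x)]
      if (length(unique(x)) < 3) next
      thr <- unname(quantile(x, runif(1, 0.2, 0.8), type = 1))
      return(rule_condition(v, sample(c("<", ">="), 1), thr))
    }
  }
  with_seed(derive_seed(seed, "sample_rules"), {
    rules <- purrr::map(seq_len(q), function(k) {
      nc <- sample(seq_len(max_conditions), 1)
      conds <- purrr::map(seq_len(nc), ~ draw_condition())
      simplify_rule(rule(dplyr::bind_rows(conds)), schema)
    })
    names(rules) <- sprintf("noise_%03d", seq_len(q))
    rules_tibble(rules, schema)
  })
}

#' Null simulation: pruning under outcome-independent rules
#'
#' Generates cohorts with the TEDDY-like covariate structure but no planted
#' rule effects, builds a pool of random noise rules, and runs the full
#' cross-validated pruning stage. Under the one-standard-error rule the
#' selection should usually be empty; the fraction of seeds selecting zero
#' rules measures the pipeline's resistance to false discoveries.
#'
#' @param n Cohort size per seed.
#' @param q Number of noise rules.
#' @param n_seeds Number of independent replicates.
#' @param seed Base seed.
#' @param k,rule Passed to [prune_rules()].
#' @return A tibble (`seed`, `n_selected`, `zero`) with attribute
#'   `zero_fraction`.
#' @export
simulate_null_selection <- function(n = 2000, q = 50, n_seeds = 20,
                                    seed = 1L, k = 10, rule = "1se") {
  base <- teddy_like_spec(n, seed = seed)
  base$planted_rules <- NULL
  base$baseline_logit <- qlogis(763 / 3757)
  out <- purrr::map_dfr(seq_len(n_seeds), function(i) {
    spec <- base
    spec$seed <- derive_seed(seed, paste0("null_cohort_", i))
    cohort <- generate_cohort(spec)
    pool <- sample_rules(spec$schema, cohort, q,
                         seed = derive_seed(seed, paste0("null_rules_", i)))
    pruned <- withCallingHandlers(
      prune_rules(pool, cohort, k = k, rule = rule,
                  seed = derive_seed(seed, paste0("null_cv_", i))),
      warning = function(w) invokeRestart("muffleWarning")
    )
    tibble::tibble(seed = i, n_selected = nrow(pruned$rules))
  })
  out$zero <- out$n_selected == 0
  attr(out, "zero_fraction") <- mean(out$zero)
  out
}

#' Recovery simulation: the full pipeline against planted rules
#'
#' For each replicate, generates a TEDDY-like cohort with the eight
#' packaged rules planted, runs forest growth, rule extraction and
#' cross-validated pruning, and matches the selected rules to the planted
#' ones by endorsement-pattern Jaccard similarity. A planted rule counts as
#' recovered when some selected rule endorses an at-least-50%-overlapping
#' subgroup; a replicate succeeds when at least half (4/8) of the planted
#' rules are recovered. Also verifies, per replicate, that every planted
#' risk-increasing rule profiles above the overall withdrawal rate.
#'
#' @param n Cohort size per replicate.
#' @param n_seeds Number of replicates.
#' @param seed Base seed.
#' @param n_trees Forest size.
#' @param jaccard_threshold Match threshold on endorsement Jaccard.
#' @return A tibble (`seed`, `q_pool`, `n_selected`, `n_recovered`,
#'   `success`, `increasing_ok`) with attributes `success_fraction` and
#'   `increasing_all_ok`.
#' @export
simulate_rule_recovery <- function(n = 10000, n_seeds = 20, seed = 1L,
                                   n_trees = 100, jaccard_threshold = 0.5) {
  planted <- teddy_rules()
  out <- purrr::map_dfr(seq_len(n_seeds), function(i) {
    spec <- teddy_like_spec(n, seed = derive_seed(seed, paste0("rec_cohort_", i)))
    cohort <- generate_cohort(spec)
    forest <- grow_forest(cohort, forest_params(
      n_trees = n_trees, seed = derive_seed(seed, paste0("rec_forest_", i))))
    pool <- extract_rules(forest)
    pruned <- withCallingHandlers(
      prune_rules(pool, cohort,
                  seed = derive_seed(seed, paste0("rec_cv_", i))),
      warning = function(w) invokeRestart("muffleWarning")
    )
    Ep <- endorsement_matrix(planted, cohort)
    n_rec <- 0L
    if (nrow(pruned$rules) > 0) {
      Es <- endorsement_matrix(pruned$rules, cohort)
      n_rec <- sum(vapply(seq_len(ncol(Ep)), function(a) {
        any(vapply(seq_len(ncol(Es)), function(b) {
          endorsement_jaccard(Ep[, a], Es[, b]) >= jaccard_threshold
        }, logical(1)))
      }, logical(1)))
    }
    prof <- profile_rules(planted, cohort)
    inc <- dplyr::filter(prof$profiles,
                         planted$direction[match(.data$rule_id,
                                                 planted$rule_id)] == "increasing")
    tibble::tibble(
      seed = i, q_pool = nrow(pool), n_selected = nrow(pruned$rules),
      n_recovered = n_rec,
      success = n_rec >= ceiling(nrow(planted) / 2),
      increasing_ok = all(inc$outcome_rate > prof$overall_rate)
    )
  })
  attr(out, "success_fraction") <- mean(out$success)
  attr(out, "increasing_all_ok") <- all(out$increasing_ok)
  out
}
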