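#' Configure an end-to-end pipeline run
#'
#' One configuration drives the whole flow: obtain a cohort (load a file or
#' generate synthetically) -> grow the forest and extract candidate rules
#' -> prune by cross-validated sparse logistic regression -> profile the
#' selected subgroups -> fit the regression baseline and compare. A single
#' global seed is expanded into independent per-stage streams, so changing
#' the forest size does not perturb the synthetic cohort.
#'
#' @param cohort_path Path to a cohort CSV/TSV (exclusive with
#'   `synthetic`).
#' @param synthetic A [synthetic_spec()] (exclusive with `cohort_path`).
#' @param schema A [covariate_schema()]; defaults to the synthetic spec's
#'   schema.
#' @param forest A [forest_params()].
#' @param prune A list of [prune_rules()] settings (`k`, `rule`, `nlambda`,
#'   `lambda_min_ratio`).
#' @param baseline A [baseline_model_spec()], or `NULL` to skip the
#'   baseline stage.
#' @param out_dir Output directory.
#' @param seed Global integer seed.
#' @param log_level `"info"` or `"quiet"`.
#' @return A validated `run_config`.
#' @export
run_config <- function(cohort_path = NULL, synthetic = NULL, schema = NULL,
                       forest = forest_params(), prune = list(),
                       baseline = teddy_baseline_spec(),
                       out_dir = tempfile("cohortrules_run_"),
                       seed = 1L, log_level = c("info", "quiet")) {
  problems <- character()
  if (is.null(cohort_path) == is.null(synthetic)) {
    problems <- c(problems, "exactly one input source required: cohort_path or synthetic")
  }
  if (!is.null(cohort_path) && !file.exists(cohort_path)) {
    problems <- c(problems, paste0("cohort file not found: ", cohort_path))
  }
  if (!is.null(synthetic) && !inherits(synthetic, "synthetic_spec")) {
    problems <- c(problems, "`synthetic` must be a synthetic_spec")
  }
  if (is.null(schema)) {
    schema <- if (!is.null(synthetic)) synthetic$schema else NULL
  }
  if (is.null(schema)) {
    problems <- c(problems, "a schema is required when loading a cohort from file")
  } else if (!inherits(schema, "covariate_schema")) {
    problems <- c(problems, "`schema` must be a covariate_schema")
  }
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    problems <- c(problems, "`seed` must be a single integer")
  }
  bad_prune <- setdiff(names(prune), c("k", "rule", "nlambda", "lambda_min_ratio", "tol"))
  if (length(bad_prune) > 0) {
    problems <- c(problems, paste0("unknown prune setting(s): ",
                                   paste(bad_prune, collapse = ", ")))
  }
  if (length(problems) > 0) {
    abort(paste0("invalid run configuration:\n",
                 paste0("  - ", problems, collapse = "\n")),
          class = "cohortrules_config_error")
  }
  structure(list(cohort_path = cohort_path, synthetic = synthetic,
                 schema = schema, forest = forest, prune = prune,
                 baseline = baseline, out_dir = out_dir,
                 seed = as.integer(seed), log_level = match.arg(log_level)),
            class = "run_config")
}

pipeline_log <- function(config, ...) {
  if (config$log_level != "quiet") {
    message(format(Sys.time(), "%H:%M:%S"), " [cohortrules] ", ...)
  }
}

run_stage <- function(config, name, timings_env, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(force(expr), error = function(e) {
    abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)),
          class = "cohortrules_stage_error", parent = e)
  })
  timings_env$timings[[name]] <- proc.time()[["elapsed"]] - t0
  res
}

#' Run the full rule-discovery pipeline
#'
#' Executes the configured stages in order, writes every stage output
#' (cohort CSV, candidate rule pool, pruned model JSON, subgroup and
#' redundancy reports, baseline coefficient table, factor-concordance
#' table) into `config$out_dir`, and returns a manifest with per-stage
#' timings and MD5 checksums of every file. A failed stage aborts with a
#' stage-named error; outputs of earlier stages are preserved.
#'
#' @param config A [run_config()].
#' @return A `run_manifest`: config hash, package version, per-stage
#'   timings, counts (cohort n, pool q, selected rule count, uncovered
#'   fraction), and the file inventory with checksums. Also written to
#'   `manifest.json`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  env <- new.env(); env$timings <- list()
  out <- config$out_dir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)

  cohort <- run_stage(config, "cohort", env, {
    if (!is.null(config$synthetic)) {
      spec <- config$synthetic
      spec$seed <- derive_seed(config$seed, "synthetic")
      co <- generate_cohort(spec)
      write_cohort(co, file.path(out, "cohort.csv"))
      co
    } else {
      load_cohort(config$cohort_path, config$schema)
    }
  })
  pipeline_log(config, "cohort: n = ", nrow(cohort))

  descr <- run_stage(config, "descriptives", env, {
    d <- descriptive_table(cohort)
    readr::write_csv(d, file.path(out, "descriptive_table.csv"), progress = FALSE)
    writeLines(format_descriptive_markdown(d),
               file.path(out, "descriptive_table.md"))
    d
  })

  pool <- run_stage(config, "rules", env, {
    fp <- config$forest
    fp$seed <- derive_seed(config$seed, "forest")
    forest <- grow_forest(cohort, fp)
    pool <- extract_rules(forest)
    write_rules(pool, file.path(out, "rule_pool.tsv"),
                schema = cohort_schema(cohort))
    pool
  })
  pipeline_log(config, "rule pool: q = ", nrow(pool))

  pruned <- run_stage(config, "prune", env, {
    args <- c(list(pool = pool, cohort = cohort,
                   seed = derive_seed(config$seed, "prune")), config$prune)
    pr <- do.call(prune_rules, args)
    write_pruned_model(pr, file.path(out, "pruned_model.json"),
                       schema = cohort_schema(cohort))
    pr
  })
  pipeline_log(config, "pruned: ", nrow(pruned$rules), " rules selected from ",
               pruned$q_in)

  prof <- run_stage(config, "profile", env, {
    if (nrow(pruned$rules) > 0) {
      p <- profile_rules(pruned$rules, cohort)
      r <- redundancy_matrix(pruned$rules, cohort)
      render_reports(p, r, out)
      list(profiles = p, redundancy = r)
    } else {
      p <- profile_rules(list(), cohort)
      render_reports(p, NULL, out, plots = FALSE)
      list(profiles = p, redundancy = NULL)
    }
  })
  pipeline_log(config, "uncovered fraction = ",
               sprintf("%.3f", prof$profiles$coverage$fraction_uncovered))

  baseline <- NULL
  if (!is.null(config$baseline)) {
    baseline <- run_stage(config, "baseline", env, {
      b <- fit_logistic_baseline(cohort, config$baseline)
      write_baseline_csv(b, file.path(out, "baseline_model.csv"))
      cmp <- compare_with_rules(b, pruned)
      readr::write_csv(cmp, file.path(out, "factor_concordance.csv"),
                       progress = FALSE)
      b
    })
    pipeline_log(config, "baseline: n_used = ", baseline$n_used,
                 ", chi-square = ", sprintf("%.1f", baseline$model_chisq))
  }

  files <- list.files(out, full.names = TRUE, recursive = TRUE)
  files <- files[basename(files) != "manifest.json"]
  manifest <- structure(list(
    package_version = as.character(utils::packageVersion("cohortrules")),
    seed = config$seed,
    config_hash = rlang::hash(config[setdiff(names(config), "out_dir")]),
    counts = list(
      cohort_n = nrow(cohort), pool_q = nrow(pool),
      n_selected = nrow(pruned$rules),
      fraction_uncovered = prof$profiles$coverage$fraction_uncovered,
      baseline_n_used = if (is.null(baseline)) NA else baseline$n_used
    ),
    timings = env$timings,
    files = tibble::tibble(file = basename(files),
                           md5 = unname(tools::md5sum(files)))
  ), class = "run_manifest")
  jsonlite::write_json(unclass(manifest), file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("<run_manifest> cohortrules ", x$package_version, ", seed ", x$seed, "\n",
      "  cohort n = ", x$counts$cohort_n, ", pool q = ", x$counts$pool_q,
      ", selected = ", x$counts$n_selected, "\n",
      "  uncovered fraction = ", sprintf("%.3f", x$counts$fraction_uncovered),
      "\n  files: ", nrow(x$files), "\n", sep = "")
  invisible(x)
}

#' Fast documented demo on the packaged rules
#'
#' Generates a TEDDY-like synthetic cohort, evaluates the eight packaged
#' risk rules directly (no learning), and produces the subgroup-rate and
#' redundancy reports. Changing the seed changes the cohort (and hence the
#' profiles) but never the fixture rules.
#'
#' @param n Cohort size.
#' @param seed Integer seed.
#' @param out_dir Optional directory for CSV/plot reports.
#' @return A list: `profiles` (a `subgroup_profiles`), `redundancy` (a
#'   `redundancy_matrix`), `cohort`.
#' @export
run_fixture_demo <- function(n = 10000, seed = 1L, out_dir = NULL) {
  spec <- teddy_like_spec(n, seed = seed)
  cohort <- generate_cohort(spec)
  rules <- teddy_rules(spec$schema)
  profiles <- profile_rules(rules, cohort)
  redundancy <- redundancy_matrix(rules, cohort)
  if (!is.null(out_dir)) render_reports(profiles, redundancy, out_dir)
  list(profiles = profiles, redundancy = redundancy, cohort = cohort)
}
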