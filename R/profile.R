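#' Profile the subgroups endorsing each rule
#'
#' For each rule: the endorsement count, the withdrawal rate among
#' endorsers, its direction versus the overall cohort rate (increasing /
#' decreasing; an exact tie is labeled neutral) and the rate ratio. Also
#' reports coverage: the fraction of the cohort endorsing no rule and the
#' withdrawal rate of that uncovered group. Rules with zero endorsers get
#' an explicitly undefined rate, never a silent zero.
#'
#' @param rules A rule set (tibble with `rule` list column, or list of
#'   rules); typically the `$rules` of a [prune_rules()] result.
#' @param cohort A cohort.
#' @return A `subgroup_profiles` object: `$profiles` tibble (`rule_id`,
#'   `text`, `n_endorsing`, `n_withdrawn`, `outcome_rate`, `direction`,
#'   `rate_ratio_vs_overall`), `$overall_rate`, `$coverage` (one-row
#'   tibble: `n_uncovered`, `fraction_uncovered`,
#'   `uncovered_outcome_rate`).
#' @export
profile_rules <- function(rules, cohort) {
  schema <- cohort_schema(cohort)
  y <- cohort[[schema_outcome(schema)]]
  n <- nrow(cohort)
  overall <- mean(y)
  E <- endorsement_matrix(rules, cohort)
  rtbl <- if (is.data.frame(rules)) rules else rules_tibble(rules)

  if (ncol(E) == 0) {
    profiles <- tibble::tibble(
      rule_id = character(), text = character(), n_endorsing = numeric(),
      n_withdrawn = numeric(), outcome_rate = numeric(),
      direction = character(), rate_ratio_vs_overall = numeric()
    )
    uncovered <- rep(TRUE, n)
    coverage <- tibble::tibble(
      n_uncovered = n, fraction_uncovered = if (n > 0) 1 else NA_real_,
      uncovered_outcome_rate = if (n > 0) mean(y) else NA_real_
    )
    return(structure(list(profiles = profiles, overall_rate = overall,
                          coverage = coverage, n = n),
                     class = "subgroup_profiles"))
  }
  profiles <- tibble::tibble(
    rule_id = colnames(E),
    text = (rtbl$text %||% purrr::map_chr(rtbl$rule, format_rule)),
    n_endorsing = unname(colSums(E)),
    n_withdrawn = as.numeric(crossprod(E, y)),
    outcome_rate = ifelse(unname(colSums(E)) > 0,
                          as.numeric(crossprod(E, y)) / unname(colSums(E)),
                          NA_real_)
  ) |>
    dplyr::mutate(
      direction = dplyr::case_when(
        .data$n_endorsing == 0 ~ "undefined",
        .data$outcome_rate > overall ~ "increasing",
        .data$outcome_rate < overall ~ "decreasing",
        TRUE ~ "neutral"
      ),
      rate_ratio_vs_overall = ifelse(.data$n_endorsing > 0 & overall > 0,
                                     .data$outcome_rate / overall, NA_real_)
    )

  uncovered <- if (ncol(E) > 0) rowSums(E) == 0 else rep(TRUE, n)
  coverage <- tibble::tibble(
    n_uncovered = sum(uncovered),
    fraction_uncovered = if (n > 0) mean(uncovered) else NA_real_,
    uncovered_outcome_rate = if (any(uncovered)) mean(y[uncovered]) else NA_real_
  )
  structure(list(profiles = profiles, overall_rate = overall,
                 coverage = coverage, n = n),
            class = "subgroup_profiles")
}

#' @export
print.subgroup_profiles <- function(x, ...) {
  cat("<subgroup_profiles> ", nrow(x$profiles), " rules, overall rate ",
      sprintf("%.3f", x$overall_rate), ", uncovered ",
      sprintf("%.1f%%", 100 * x$coverage$fraction_uncovered), "\n", sep = "")
  print(x$profiles)
  invisible(x)
}

#' @method tidy subgroup_profiles
#' @export
tidy.subgroup_profiles <- function(x, ...) x$profiles

#' @method glance subgroup_profiles
#' @export
glance.subgroup_profiles <- function(x, ...) {
  tibble::tibble(n = x$n, n_rules = nrow(x$profiles),
                 overall_rate = x$overall_rate,
                 fraction_uncovered = x$coverage$fraction_uncovered,
                 uncovered_outcome_rate = x$coverage$uncovered_outcome_rate)
}

#' @method autoplot subgroup_profiles
#' @export
autoplot.subgroup_profiles <- function(object, ...) {
  tbl <- dplyr::filter(object$profiles, .data$n_endorsing > 0)
  ggplot2::ggplot(tbl, ggplot2::aes(x = .data$rule_id, y = .data$outcome_rate,
                                    fill = .data$direction)) +
    ggplot2::geom_col() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n_endorsing), vjust = -0.4,
                       size = 3) +
    ggplot2::geom_hline(yintercept = object$overall_rate, linetype = 2) +
    ggplot2::scale_fill_manual(values = c(increasing = "#b2182b",
                                          decreasing = "#2166ac",
                                          neutral = "grey60")) +
    ggplot2::labs(x = NULL, y = "withdrawal rate",
                  title = "Subgroup withdrawal rates",
                  subtitle = "dashed line: overall rate; labels: subgroup size")
}

#' Pairwise endorsement redundancy of a rule set
#'
#' `M[i, j]` is the proportion of the endorsers of rule *i* who also
#' endorse rule *j*, computed from integer joint endorsement counts. The
#' diagonal is exactly 1 wherever rule *i* has endorsers; rows of rules
#' with no endorsers are flagged undefined (NA). The integer identity
#' `M[i, j] * n_i = M[j, i] * n_j` (= the joint count) holds exactly.
#'
#' @param rules A rule set (>= 1 rule).
#' @param cohort A cohort.
#' @return A `redundancy_matrix`: `$M` (q x q), `$n_endorsing`, `$joint`
#'   (integer joint counts).
#' @export
redundancy_matrix <- function(rules, cohort) {
  E <- endorsement_matrix(rules, cohort)
  if (ncol(E) == 0) {
    abort("redundancy_matrix needs at least one rule", class = "cohortrules_value_error")
  }
  joint <- crossprod(E)               # integer joint endorsement counts
  n_i <- diag(joint)
  M <- sweep(joint, 1, n_i, "/")      # row i divided by its endorser count
  M[n_i == 0, ] <- NA_real_
  dimnames(M) <- dimnames(joint) <- list(colnames(E), colnames(E))
  structure(list(M = M, n_endorsing = setNames(as.numeric(n_i), colnames(E)),
                 joint = joint),
            class = "redundancy_matrix")
}

#' @export
print.redundancy_matrix <- function(x, ...) {
  cat("<redundancy_matrix> ", nrow(x$M), " rules\n", sep = "")
  print(round(x$M, 3))
  invisible(x)
}

#' @method tidy redundancy_matrix
#' @export
tidy.redundancy_matrix <- function(x, ...) {
  tibble::as_tibble(x$M, rownames = "rule_i") |>
    tidyr::pivot_longer(-"rule_i", names_to = "rule_j",
                        values_to = "overlap_proportion")
}

#' @method autoplot redundancy_matrix
#' @export
autoplot.redundancy_matrix <- function(object, ...) {
  tbl <- tidy(object)
  ggplot2::ggplot(tbl, ggplot2::aes(x = .data$rule_j, y = .data$rule_i,
                                    fill = .data$overlap_proportion)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.2f", .data$overlap_proportion)), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "#b2182b",
                                 limits = c(0, 1)) +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::labs(x = "also endorses rule j", y = "endorsers of rule i",
                  fill = "proportion",
                  title = "Pairwise rule redundancy")
}

#' Write profiling reports to disk
#'
#' Writes the subgroup profiles, the redundancy matrix and the coverage
#' report as CSV (numbers exactly as computed) plus bar-chart and
#' matrix-plot images. The CSVs are the source of truth; plots are
#' conveniences.
#'
#' @param profiles A `subgroup_profiles` object.
#' @param redundancy A `redundancy_matrix` object (or `NULL` to skip).
#' @param out_dir Output directory (created if needed).
#' @param plots Write PNG plots too?
#' @return Invisibly, the vector of files written.
#' @export
render_reports <- function(profiles, redundancy, out_dir, plots = TRUE) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(paste0("cannot create output directory: ", out_dir),
                   class = "cohortrules_io_error")
  }
  files <- character()
  f <- file.path(out_dir, "subgroup_profiles.csv")
  readr::write_csv(profiles$profiles, f, progress = FALSE)
  files <- c(files, f)
  f <- file.path(out_dir, "coverage.csv")
  readr::write_csv(
    dplyr::mutate(profiles$coverage, overall_rate = profiles$overall_rate),
    f, progress = FALSE)
  files <- c(files, f)
  if (!is.null(redundancy)) {
    f <- file.path(out_dir, "redundancy_matrix.csv")
    readr::write_csv(tibble::as_tibble(redundancy$M, rownames = "rule_id"),
                     f, progress = FALSE)
    files <- c(files, f)
  }
  if (plots && nrow(profiles$profiles) > 0) {
    f <- file.path(out_dir, "subgroup_rates.png")
    ggplot2::ggsave(f, autoplot(profiles), width = 7, height = 4.5, dpi = 120)
    files <- c(files, f)
    if (!is.null(redundancy)) {
      f <- file.path(out_dir, "redundancy_matrix.png")
      ggplot2::ggsave(f, autoplot(redundancy), width = 6.5, height = 5.5, dpi = 120)
      files <- c(files, f)
    }
  }
  invisible(files)
}
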