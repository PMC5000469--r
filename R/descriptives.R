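#' Contingency cells and withdrawal rates
#'
#' A contingency cell is one stratum of an actives-vs-withdrawals table:
#' the count of participants still active and the count withdrawn. The
#' withdrawal rate of a cell is withdrawn / (active + withdrawn).
#'
#' @param stratum_label Label for the stratum (e.g. `"smoked"`).
#' @param n_active,n_withdrawn Non-negative counts.
#' @return `contingency_cell()` returns a one-row tibble;
#'   `withdrawal_rate()` a numeric vector of proportions in \[0, 1\].
#' @export
#' @examples
#' withdrawal_rate(contingency_cell("smoked", 296, 171)) # 0.366
contingency_cell <- function(stratum_label, n_active, n_withdrawn) {
  if (any(n_active < 0) || any(n_withdrawn < 0)) {
    abort("contingency counts must be non-negative", class = "cohortrules_value_error")
  }
  tibble::tibble(stratum_label = as.character(stratum_label),
                 n_active = as.numeric(n_active),
                 n_withdrawn = as.numeric(n_withdrawn))
}

#' @rdname contingency_cell
#' @param cell A data frame with columns `n_active` and `n_withdrawn` (one
#'   row per stratum), as returned by [contingency_cell()].
#' @export
withdrawal_rate <- function(cell) {
  tot <- cell$n_active + cell$n_withdrawn
  if (any(tot <= 0)) {
    abort("withdrawal rate undefined: zero participants in stratum",
          class = "cohortrules_value_error")
  }
  cell$n_withdrawn / tot
}

#' Crude odds ratio between two contingency cells
#'
#' Computes the unadjusted odds ratio of withdrawal for an exposed versus an
#' unexposed stratum, with a 95% Wald interval on the log-odds-ratio scale
#' (standard error = sqrt of the summed reciprocal counts). Zero cells are an
#' error: no continuity correction is applied silently.
#'
#' @param exposed,unexposed One-row data frames with `n_active`,
#'   `n_withdrawn` (see [contingency_cell()]).
#' @param conf_level Confidence level (default 0.95).
#' @return A one-row tibble: `odds_ratio`, `log_or`, `se`, `conf_low`,
#'   `conf_high`.
#' @export
#' @examples
#' crude_odds_ratio(contingency_cell("smoked", 296, 171),
#'                  contingency_cell("did_not_smoke", 2602, 510))
crude_odds_ratio <- function(exposed, unexposed, conf_level = 0.95) {
  a_e <- exposed$n_active[1]; w_e <- exposed$n_withdrawn[1]
  a_u <- unexposed$n_active[1]; w_u <- unexposed$n_withdrawn[1]
  counts <- c(a_e, w_e, a_u, w_u)
  if (any(counts <= 0)) {
    abort("crude odds ratio undefined with a zero cell (no continuity correction applied)",
          class = "cohortrules_value_error")
  }
  log_or <- log((w_e * a_u) / (a_e * w_u))
  se <- sqrt(sum(1 / counts))
  z <- qnorm(1 - (1 - conf_level) / 2)
  tibble::tibble(
    odds_ratio = exp(log_or), log_or = log_or, se = se,
    conf_low = exp(log_or - z * se), conf_high = exp(log_or + z * se)
  )
}

#' Descriptive actives-vs-withdrawals table
#'
#' Summarizes every schema covariate stratified by the outcome: counts and
#' row percents per level for categorical variables (with an explicit
#' missing-data row), mean and SD per stratum for continuous and count
#' variables (plus a missing-data count row when any value is missing).
#' Percents are row-normalized within each level, i.e. the active and
#' withdrawn percents of one level sum to 100.
#'
#' @param cohort A cohort.
#' @return A tibble with one row per variable level (or per `mean_sd`
#'   summary): `variable`, `level`, `statistic`, `n_active`, `pct_active`,
#'   `n_withdrawn`, `pct_withdrawn`, `n_total`, `mean_active`, `sd_active`,
#'   `mean_withdrawn`, `sd_withdrawn`, `mean_total`, `sd_total`.
#' @export
descriptive_table <- function(cohort) {
  if (nrow(cohort) == 0) {
    abort("descriptive_table needs a non-empty cohort", class = "cohortrules_value_error")
  }
  schema <- cohort_schema(cohort)
  y <- cohort[[schema_outcome(schema)]]

  purrr::map_dfr(seq_len(nrow(schema)), function(i) {
    v <- schema$variable[i]
    x <- cohort[[v]]
    if (schema$kind[i] == "categorical") {
      levs <- c(schema$levels[[i]], "(missing)")
      xx <- ifelse(is.na(x), "(missing)", x)
      purrr::map_dfr(levs, function(l) {
        sel <- xx == l
        if (l == "(missing)" && !any(sel)) return(NULL)
        tibble::tibble(
          variable = v, level = l, statistic = "n_pct",
          n_active = sum(sel & y == 0), n_withdrawn = sum(sel & y == 1),
          n_total = sum(sel)
        )
      })
    } else {
      rows <- tibble::tibble(
        variable = v, level = "all", statistic = "mean_sd",
        n_active = sum(!is.na(x) & y == 0), n_withdrawn = sum(!is.na(x) & y == 1),
        n_total = sum(!is.na(x)),
        mean_active = mean(x[y == 0], na.rm = TRUE),
        sd_active = sd(x[y == 0], na.rm = TRUE),
        mean_withdrawn = mean(x[y == 1], na.rm = TRUE),
        sd_withdrawn = sd(x[y == 1], na.rm = TRUE),
        mean_total = mean(x, na.rm = TRUE), sd_total = sd(x, na.rm = TRUE)
      )
      if (anyNA(x)) {
        rows <- dplyr::bind_rows(rows, tibble::tibble(
          variable = v, level = "(missing)", statistic = "n_pct",
          n_active = sum(is.na(x) & y == 0), n_withdrawn = sum(is.na(x) & y == 1),
          n_total = sum(is.na(x))
        ))
      }
      rows
    }
  }) |>
    dplyr::mutate(
      pct_active = ifelse(.data$statistic == "n_pct" & .data$n_total > 0,
                          100 * .data$n_active / .data$n_total, NA_real_),
      pct_withdrawn = ifelse(.data$statistic == "n_pct" & .data$n_total > 0,
                             100 * .data$n_withdrawn / .data$n_total, NA_real_),
      .after = "n_total"
    )
}

# Integer percent display, rounding half away from zero (so 16.5 -> 17),
# matching the usual epidemiological table formatting.
percent_display <- function(p) {
  sign(p) * floor(abs(p) + 0.5)
}

#' Render a descriptive table as markdown
#'
#' @param tbl Output of [descriptive_table()].
#' @return A character vector of markdown lines.
#' @export
format_descriptive_markdown <- function(tbl) {
  header <- c("| Variable | Level | Actives | Withdrawals | Total |",
              "|---|---|---|---|---|")
  body <- purrr::pmap_chr(tbl, function(...) {
    r <- list(...)
    if (r$statistic == "n_pct") {
      sprintf("| %s | %s | %d (%d%%) | %d (%d%%) | %d |",
              r$variable, r$level, r$n_active, percent_display(r$pct_active),
              r$n_withdrawn, percent_display(r$pct_withdrawn), r$n_total)
    } else {
      sprintf("| %s | M (SD) | %.1f (%.1f) | %.1f (%.1f) | %.1f (%.1f) |",
              r$variable, r$mean_active, r$sd_active,
              r$mean_withdrawn, r$sd_withdrawn, r$mean_total, r$sd_total)
    }
  })
  c(header, body)
}
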