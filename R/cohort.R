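#' Build a cohort from a participant-level data frame
#'
#' Validates every column against the schema (kinds, categorical levels,
#' binary outcome), recomputes derived covariates (the per-record count of
#' missing covariate cells), and returns a tidy cohort ready for the rule
#' pipeline. Missing covariate cells are `NA`; the outcome may never be
#' missing.
#'
#' @param data A data frame with one row per participant. Must contain every
#'   non-derived schema covariate and the outcome column.
#' @param schema A [covariate_schema()].
#'
#' @return A `cohort`: a tibble with validated covariate columns, a
#'   `missing_count` column (when the schema declares one) and the 0/1
#'   outcome, with the schema attached as an attribute.
#' @export
as_cohort <- function(data, schema) {
  data <- tibble::as_tibble(data)
  outcome <- schema_outcome(schema)
  base_vars <- schema$variable[!schema$derived]

  missing_cols <- setdiff(c(base_vars, outcome), names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("cohort is missing column(s): ", paste(missing_cols, collapse = ", ")),
          class = "cohortrules_schema_error")
  }

  out <- tibble::tibble(.rows = nrow(data))
  for (i in seq_len(nrow(schema))) {
    v <- schema$variable[i]
    if (schema$derived[i]) next
    col <- data[[v]]
    if (schema$kind[i] == "categorical") {
      col <- as.character(col)
      col[!is.na(col) & col == ""] <- NA_character_
      bad <- !is.na(col) & !col %in% schema$levels[[i]]
      if (any(bad)) {
        abort(paste0("column '", v, "': value(s) outside declared levels at row(s) ",
                     paste(head(which(bad), 5), collapse = ", ")),
              class = "cohortrules_schema_error")
      }
    } else {
      col <- suppressWarnings(as.numeric(col))
      was_na <- is.na(data[[v]]) | (is.character(data[[v]]) & data[[v]] == "")
      if (any(is.na(col) & !was_na)) {
        abort(paste0("column '", v, "': non-numeric value(s) in a ",
                     schema$kind[i], " variable"),
              class = "cohortrules_schema_error")
      }
      if (schema$kind[i] == "count" && any(col < 0 | col != floor(col), na.rm = TRUE)) {
        abort(paste0("column '", v, "': counts must be non-negative integers"),
              class = "cohortrules_schema_error")
      }
    }
    out[[v]] <- col
  }

  y <- data[[outcome]]
  if (is.character(y)) y <- suppressWarnings(as.numeric(y))
  if (anyNA(y)) {
    abort(paste0("outcome '", outcome, "' has missing value(s) at row(s) ",
                 paste(head(which(is.na(y)), 5), collapse = ", ")),
          class = "cohortrules_schema_error")
  }
  if (!all(y %in% c(0, 1))) {
    abort(paste0("outcome '", outcome, "' must be coded 0/1 (1 = withdrawn); ",
                 "offending row(s): ",
                 paste(head(which(!y %in% c(0, 1)), 5), collapse = ", ")),
          class = "cohortrules_schema_error")
  }

  # derived covariates: missing-data count over the non-derived covariates
  mc <- missing_cell_count(out[, intersect(base_vars, names(out)), drop = FALSE])
  for (i in which(schema$derived)) {
    out[[schema$variable[i]]] <- mc
  }
  out[[outcome]] <- as.integer(y)

  structure(out, schema = schema, class = c("cohort", class(tibble::tibble())))
}

missing_cell_count <- function(df) {
  if (ncol(df) == 0) return(integer(nrow(df)))
  as.integer(rowSums(is.na(df)))
}

#' @export
print.cohort <- function(x, ...) {
  s <- cohort_schema(x)
  n_w <- sum(x[[schema_outcome(s)]])
  cat("<cohort> ", nrow(x), " participants, ", n_w, " withdrawn (",
      if (nrow(x) > 0) sprintf("%.1f%%", 100 * n_w / nrow(x)) else "-",
      ")\n", sep = "")
  NextMethod()
  invisible(x)
}

#' Schema attached to a cohort
#' @param cohort A cohort built by [as_cohort()], [load_cohort()] or
#'   [generate_cohort()].
#' @return The [covariate_schema()].
#' @export
cohort_schema <- function(cohort) {
  s <- attr(cohort, "schema", exact = TRUE)
  if (is.null(s)) abort("not a cohort: no schema attribute",
                        class = "cohortrules_schema_error")
  s
}

#' Load a cohort from a delimited text file
#'
#' Reads a CSV/TSV with a header row, maps empty cells to missing, validates
#' against the schema and populates the derived missing-data count. The
#' delimiter is inferred from the file extension (`.tsv` = tab, otherwise
#' comma).
#'
#' @param path Path to the delimited file.
#' @param schema A [covariate_schema()].
#' @return A cohort tibble (see [as_cohort()]).
#' @export
load_cohort <- function(path, schema) {
  if (!file.exists(path)) {
    abort(paste0("cannot read cohort file: ", path), class = "cohortrules_io_error")
  }
  delim <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  data <- readr::read_delim(path, delim = delim, col_types = readr::cols(.default = "c"),
                            na = c(""), progress = FALSE)
  as_cohort(data, schema)
}

#' Write a cohort back to delimited text
#'
#' Missing cells are written as empty strings; derived covariates are written
#' too (they are recomputed, and checked, on reload).
#'
#' @param cohort A cohort.
#' @param path Output path (`.tsv` for tab-delimited, else CSV).
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  delim <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  readr::write_delim(tibble::as_tibble(cohort), path, delim = delim, na = "")
  invisible(path)
}
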