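#' Specify the outcome and covariates for association testing
#'
#' Bundles the per-sample outcome vector `X`, its kind, and any
#' microbiome-unrelated covariates `U` used by the null model / design.
#'
#' @param kind One of `"continuous"`, `"binary"`, `"categorical"`,
#'   `"survival"`.
#' @param values Per-sample outcome. Continuous: numeric. Binary: 0/1,
#'   logical, or a two-level factor/character (coded to 0/1 with the coding
#'   messaged). Categorical: factor/character with >= 2 levels. Survival:
#'   positive event/censoring times (see `event`).
#' @param event For `kind = "survival"`, the 0/1 event indicator.
#' @param covariates Optional data frame of numeric or factor covariates,
#'   one row per sample.
#' @param sample_ids Optional sample identifiers.
#' @return An `outcome_spec` object.
#' @export
outcome_spec <- function(kind = c("continuous", "binary", "categorical",
                                  "survival"),
                         values, event = NULL, covariates = NULL,
                         sample_ids = NULL) {
  kind <- arg_match(kind)
  n <- length(values)
  if (n < 2) abort("need at least two samples")
  coding <- NULL
  if (kind == "binary") {
    if (is.logical(values)) values <- as.integer(values)
    if (!is.numeric(values)) {
      f <- factor(values)
      if (nlevels(f) != 2) {
        abort("binary outcome must have exactly two levels")
      }
      coding <- setNames(c(0L, 1L), levels(f))
      inform(sprintf("binary outcome coded %s=0, %s=1",
                     levels(f)[1], levels(f)[2]))
      values <- as.integer(f) - 1L
    }
    if (!all(values %in% c(0, 1))) abort("binary outcome must be 0/1")
  } else if (kind == "categorical") {
    values <- factor(values)
    tab <- table(values)
    if (length(tab) < 2 || any(tab < 1)) {
      abort("categorical outcome needs >= 2 levels, each with >= 1 sample")
    }
  } else if (kind == "survival") {
    values <- as.numeric(values)
    if (any(!is.finite(values)) || any(values <= 0)) {
      abort("survival times must be finite and strictly positive")
    }
    if (is.null(event)) abort("survival outcome requires an event indicator")
    event <- as.numeric(event)
    if (length(event) != n || !all(event %in% c(0, 1))) {
      abort("event indicator must be 0/1 and match the outcome length")
    }
  } else {
    values <- as.numeric(values)
    if (any(!is.finite(values))) abort("continuous outcome must be finite")
  }
  if (!is.null(covariates)) {
    covariates <- tibble::as_tibble(covariates)
    if (nrow(covariates) != n) {
      abort("covariates must have one row per sample")
    }
  }
  if (!is.null(sample_ids) && length(sample_ids) != n) {
    abort("sample_ids length must match the outcome")
  }
  structure(
    list(kind = kind, values = values, event = event,
         covariates = covariates,
         sample_ids = as.character(sample_ids %||% seq_len(n)),
         coding = coding),
    class = "outcome_spec"
  )
}

#' @export
print.outcome_spec <- function(x, ...) {
  cat(sprintf(
    "<outcome_spec> %s outcome, n = %d%s%s\n", x$kind, length(x$values),
    if (x$kind == "survival") {
      sprintf(" (%d events)", sum(x$event))
    } else "",
    if (!is.null(x$covariates)) {
      sprintf(", %d covariate(s)", ncol(x$covariates))
    } else ""
  ))
  invisible(x)
}

#' Read sample metadata and build an outcome specification
#'
#' Reads a tab-separated metadata file (first column = sample id, `#`
#' comment lines ignored) and, when a count table is supplied, aligns the
#' outcome to the table's sample order by id intersection — never by
#' position. Samples present on only one side are dropped with a warning.
#'
#' @param path Metadata file path.
#' @param outcome_column Column holding the outcome (for survival: the time).
#' @param outcome_kind One of continuous, binary, categorical, survival.
#' @param covariate_columns Optional character vector of covariate columns.
#' @param event_column For survival outcomes, the 0/1 event column.
#' @param table Optional [count_table] to align sample order against.
#' @return An [outcome_spec]. When `table` is given, the possibly subset
#'   table is attached as attribute `"table"`.
#' @export
read_metadata <- function(path, outcome_column,
                          outcome_kind = c("continuous", "binary",
                                           "categorical", "survival"),
                          covariate_columns = NULL, event_column = NULL,
                          table = NULL) {
  outcome_kind <- arg_match(outcome_kind)
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                        progress = FALSE)
  if (!outcome_column %in% names(df)) {
    abort(sprintf("outcome column '%s' not found in metadata", outcome_column))
  }
  if (outcome_kind == "survival" && is.null(event_column)) {
    abort("survival outcome requires event_column")
  }
  if (!is.null(event_column) && !event_column %in% names(df)) {
    abort(sprintf("event column '%s' not found in metadata", event_column))
  }
  missing_cov <- setdiff(covariate_columns %||% character(0), names(df))
  if (length(missing_cov)) {
    abort(paste("covariate column(s) not found:",
                paste(missing_cov, collapse = ", ")))
  }
  ids <- as.character(df[[1]])
  if (!is.null(table)) {
    keep <- intersect(rownames(table), ids)
    drop_meta <- setdiff(ids, keep)
    drop_counts <- setdiff(rownames(table), keep)
    if (length(drop_meta)) {
      warn(paste("dropping metadata samples absent from counts:",
                 paste(drop_meta, collapse = ", ")))
    }
    if (length(drop_counts)) {
      warn(paste("dropping count-table samples absent from metadata:",
                 paste(drop_counts, collapse = ", ")))
    }
    if (length(keep) < 2) abort("fewer than two samples shared")
    df <- df[match(keep, ids), , drop = FALSE]
    ids <- keep
    table <- table[keep, , drop = FALSE]
  }
  out <- outcome_spec(
    kind = outcome_kind,
    values = df[[outcome_column]],
    event = if (!is.null(event_column)) df[[event_column]],
    covariates = if (length(covariate_columns)) {
      df[, covariate_columns, drop = FALSE]
    },
    sample_ids = ids
  )
  if (!is.null(table)) attr(out, "table") <- table
  out
}
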