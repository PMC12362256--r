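#' Construct a sample-by-feature count table
#'
#' The count table is the package's central data object: an `n x m`
#' nonnegative integer matrix `Z` whose rows are samples and whose columns
#' are the finest-resolution features (ASVs/OTUs), i.e. the leaves of the
#' taxonomy tree. Rows and columns carry unique identifiers.
#'
#' @param x A numeric matrix (samples in rows), or a data frame whose first
#'   column holds sample identifiers and whose remaining columns are numeric
#'   feature counts.
#' @param sample_ids,feature_ids Optional identifier vectors overriding the
#'   dimnames of `x`.
#' @return A `count_table`: an integer matrix with `sample_ids` as rownames
#'   and `feature_ids` as colnames.
#' @examples
#' z <- count_table(matrix(c(5, 1, 0, 3), 2,
#'   dimnames = list(c("s1", "s2"), c("f1", "f2"))
#' ))
#' n_samples(z)
#' @export
count_table <- function(x, sample_ids = NULL, feature_ids = NULL) {
  if (is.data.frame(x)) {
    sample_ids <- sample_ids %||% as.character(x[[1]])
    m <- as.matrix(x[, -1, drop = FALSE])
    storage.mode(m) <- "double"
    x <- m
  }
  if (!is.matrix(x)) abort("counts must be a matrix or data frame")
  sample_ids <- as.character(sample_ids %||% rownames(x) %||%
    paste0("sample", seq_len(nrow(x))))
  feature_ids <- as.character(feature_ids %||% colnames(x) %||%
    paste0("feature", seq_len(ncol(x))))
  if (length(sample_ids) != nrow(x) || length(feature_ids) != ncol(x)) {
    abort("identifier lengths do not match count dimensions")
  }
  if (anyDuplicated(sample_ids)) {
    abort(paste0("duplicate sample id: ",
                 sample_ids[duplicated(sample_ids)][1]))
  }
  if (anyDuplicated(feature_ids)) {
    abort(paste0("duplicate feature id: ",
                 feature_ids[duplicated(feature_ids)][1]))
  }
  bad <- which(!is.finite(x) | x < 0 | x != round(x))
  if (length(bad)) {
    i <- arrayInd(bad[1], dim(x))
    abort(sprintf(
      "count for sample '%s', feature '%s' is not a nonnegative integer (%s)",
      sample_ids[i[1]], feature_ids[i[2]], format(x[bad[1]])
    ))
  }
  storage.mode(x) <- "integer"
  dimnames(x) <- list(sample_ids, feature_ids)
  structure(x, class = c("count_table", "matrix", "array"))
}

#' @rdname count_table
#' @export
is_count_table <- function(x) inherits(x, "count_table")

#' @rdname count_table
#' @export
n_samples <- function(x) nrow(x)

#' @rdname count_table
#' @export
n_features <- function(x) ncol(x)

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf(
    "<count_table> %d samples x %d features, total %s reads\n",
    nrow(x), ncol(x), format(sum(as.numeric(x)), big.mark = ",")
  ))
  invisible(x)
}

# keep class when subsetting with drop = FALSE
#' @export
`[.count_table` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod(drop = drop)
  if (is.matrix(out)) class(out) <- c("count_table", "matrix", "array")
  out
}

#' Read a count table from a tab-separated file
#'
#' Expects one header row and one leading label column; `#`-prefixed lines
#' are treated as comments. Orientation is normalized so that the returned
#' table is always samples x features.
#'
#' @param path File path.
#' @param orientation `"samples_as_rows"` (default) or `"features_as_rows"`.
#' @return A [count_table].
#' @export
read_count_table <- function(path,
                             orientation = c("samples_as_rows",
                                             "features_as_rows")) {
  orientation <- arg_match(orientation)
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                        progress = FALSE)
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(!vapply(df[-1], is.numeric, logical(1)))[1]
    cell <- which(is.na(suppressWarnings(as.numeric(df[[bad + 1]]))))[1]
    abort(sprintf("non-numeric cell at row '%s', column '%s'",
                  ids[cell %||% 1], names(df)[bad + 1]))
  }
  rownames(m) <- ids
  if (orientation == "features_as_rows") m <- t(m)
  count_table(m)
}

#' Write a CAT results table to a tab-separated file
#'
#' @param results A tibble of per-taxon results as produced by
#'   [cat_test_many()] (columns `taxon`, `rank`, `n_leaves`, `r2_original`,
#'   `r2_perm_mean`, `p_value`, `B`, `seed`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  if (!is.data.frame(results) || nrow(results) == 0) {
    abort("results must be a nonempty data frame")
  }
  cols <- c("taxon", "rank", "n_leaves", "r2_original", "r2_perm_mean",
            "p_value", "B", "seed")
  missing <- setdiff(cols, names(results))
  if (length(missing)) {
    abort(paste("results is missing columns:", paste(missing, collapse = ", ")))
  }
  readr::write_tsv(results[, cols], path)
  invisible(path)
}
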