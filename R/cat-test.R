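#' Permute the counts of a taxon's leaf features
#'
#' The permutation at the heart of CAT: within each leaf column of the
#' taxon under test, counts are shuffled across samples, destroying any
#' sample-outcome association carried by that taxon while leaving every
#' other feature untouched and preserving each shuffled column's multiset
#' of values.
#'
#' @param table A [count_table].
#' @param leaves Nonempty character vector of feature ids to permute.
#' @param mode `"per_column"` (default): each selected column gets an
#'   independent permutation. `"joint"`: one shared sample permutation is
#'   applied to the whole leaf block, preserving within-taxon correlation.
#' @return A [count_table] with the selected columns permuted.
#' @export
permute_taxon <- function(table, leaves, mode = c("per_column", "joint")) {
  mode <- arg_match(mode)
  if (length(leaves) == 0) abort("empty leaf set")
  cols <- match(leaves, colnames(table))
  if (anyNA(cols)) {
    abort(sprintf("feature '%s' is not a column of the count table",
                  leaves[is.na(cols)][1]))
  }
  n <- nrow(table)
  out <- unclass(table)
  if (mode == "joint") {
    out[, cols] <- out[sample.int(n), cols, drop = FALSE]
  } else {
    for (j in cols) out[, j] <- out[sample.int(n), j]
  }
  class(out) <- c("count_table", "matrix", "array")
  out
}

#' Empirical p-value from permuted R-squared values
#'
#' @param r2_original Observed global-test R-squared.
#' @param r2_perm Vector of B permuted R-squared values.
#' @param tie_rule `"add_one_tie_inclusive"` (default):
#'   `p = (1 + #\{R2_b >= R2\}) / (B + 1)`, valid at finite B and sane for
#'   degenerate taxa. `"strict_paper"`: `p = mean(R2 - R2_b < 0)`, the
#'   plain proportion with a strict inequality.
#' @return The empirical p-value.
#' @export
empirical_pvalue <- function(r2_original, r2_perm,
                             tie_rule = c("add_one_tie_inclusive",
                                          "strict_paper")) {
  tie_rule <- arg_match(tie_rule)
  if (length(r2_perm) == 0) abort("no permuted values supplied")
  if (tie_rule == "strict_paper") {
    mean(r2_original - r2_perm < 0)
  } else {
    (1 + sum(r2_perm >= r2_original)) / (length(r2_perm) + 1)
  }
}

# engine/metric plumbing shared by cat_test and cat_test_many: closures
# that turn a (possibly permuted) count table into the engine R^2,
# maximised over metrics. Everything outcome-side is computed once here.
cat_setup <- function(table, tree, outcome, metrics, engine,
                      unifrac_normalized = FALSE) {
  if (engine == "permanova") {
    if (inherits(outcome, "outcome_spec") && outcome$kind == "survival") {
      abort("survival outcomes require engine = 'mirkat'")
    }
    design_full <- build_design(outcome)
    covs <- if (inherits(outcome, "outcome_spec")) outcome$covariates
    if (!is.null(covs)) {
      h_full <- hat_matrix(design_full)
      h_red <- hat_matrix(stats::model.matrix(~., data = as.data.frame(covs)))
      r2_fun <- function(g) (sum(h_full * g) - sum(h_red * g)) / sum(diag(g))
    } else {
      h_full <- hat_matrix(design_full)
      r2_fun <- function(g) sum(h_full * g) / sum(diag(g))
    }
  } else {
    fit <- mirkat_null_fit(outcome)
    r2_fun <- function(g) mirkat_q(fit$residuals, fit$phi, g)$r2_kernel
  }
  metric_funs <- lapply(metrics, function(m) {
    metric_function(m, table = table, tree = tree,
                    unifrac_normalized = unifrac_normalized)
  })
  function(z) {
    max_over_metrics(vapply(
      metric_funs, function(f) r2_fun(gower_center(f(z))), numeric(1)
    ))
  }
}

#' CAT: conditional association test for one taxon
#'
#' Tests whether a taxon adds information about the outcome beyond what
#' the rest of the community already explains. The observed global-test
#' R-squared is compared to its distribution over B datasets in which the
#' taxon's leaf counts have been permuted across samples: a taxon whose
#' permutation barely moves R-squared carries no added signal, while a
#' conditionally associated taxon shows a drop. The outcome itself is
#' never permuted, and the outcome-side null fit is computed once.
#'
#' @param table A [count_table].
#' @param taxonomy A [taxonomy] tree over the table's features.
#' @param tree Optional [ape::phylo] tree (required for UniFrac metrics).
#' @param outcome An [outcome_spec] (or grouping vector for the PERMANOVA
#'   engine).
#' @param taxon Taxon to test (see [leaf_descendants()] for resolution).
#' @param metrics Character vector from `braycurtis`, `jaccard`,
#'   `unifrac`, `wunifrac`, `euclidean`; with several metrics the maximum
#'   R-squared per dataset is used.
#' @param engine `"permanova"` (grouping/continuous/categorical outcomes,
#'   sequential R-squared when covariates are present) or `"mirkat"`
#'   (kernel score engine; continuous, binary or survival outcomes).
#' @param b Number of permuted datasets (default 999).
#' @param seed Optional master seed; the taxon's permutation stream is
#'   derived from it so results do not depend on evaluation order.
#' @param tie_rule,permute_mode See [empirical_pvalue()] and
#'   [permute_taxon()].
#' @param unifrac_normalized Use the normalized weighted-UniFrac variant.
#' @return A `cat_result` object; see [glance.cat_result()].
#' @examples
#' sim <- simulate_dataset(m = 24, n_per_group = 8, depth = 500, seed = 1)
#' res <- cat_test(sim$table, sim$taxonomy, sim$tree,
#'   outcome_spec("binary", sim$group),
#'   taxon = taxa_at_rank(sim$taxonomy, "family")$taxon[1],
#'   metrics = "braycurtis", b = 49, seed = 7
#' )
#' glance(res)
#' @export
cat_test <- function(table, taxonomy, tree = NULL, outcome, taxon,
                     metrics = "braycurtis",
                     engine = c("permanova", "mirkat"), b = 999,
                     seed = NULL,
                     tie_rule = c("add_one_tie_inclusive", "strict_paper"),
                     permute_mode = c("per_column", "joint"),
                     unifrac_normalized = FALSE) {
  engine <- arg_match(engine)
  tie_rule <- arg_match(tie_rule)
  permute_mode <- arg_match(permute_mode)
  if (b < 1) abort("b must be >= 1")
  run_fun <- cat_setup(table, tree, outcome, metrics, engine,
                       unifrac_normalized)
  cat_test_impl(table, taxonomy, taxon, run_fun, b, seed, tie_rule,
                permute_mode, engine, metrics)
}

cat_test_impl <- function(table, taxonomy, taxon, run_fun, b, seed,
                          tie_rule, permute_mode, engine, metrics,
                          r2_original = NULL) {
  leaves <- leaf_descendants(taxonomy, taxon)
  missing <- setdiff(leaves, colnames(table))
  if (length(missing)) {
    abort(sprintf("taxonomy leaf '%s' is not a count-table feature",
                  missing[1]))
  }
  r2_original <- r2_original %||% run_fun(table)
  draw <- function() {
    vapply(seq_len(b), function(i) {
      run_fun(permute_taxon(table, leaves, permute_mode))
    }, numeric(1))
  }
  r2_perm <- if (is.null(seed)) {
    draw()
  } else {
    with_seed(derive_seed(seed, taxon), draw())
  }
  structure(
    list(
      taxon = taxon, rank = taxon_rank(taxonomy, taxon),
      leaves = leaves, r2_original = r2_original, r2_perm = r2_perm,
      p_value = empirical_pvalue(r2_original, r2_perm, tie_rule),
      b = b, seed = seed, tie_rule = tie_rule, engine = engine,
      metrics = metrics, permute_mode = permute_mode
    ),
    class = "cat_result"
  )
}

#' @export
print.cat_result <- function(x, ...) {
  cat(sprintf(
    paste0("<cat_result> taxon '%s' (%s, %d leaves)\n",
           "  R2 original = %.4f, mean permuted R2 = %.4f\n",
           "  p = %.4g  (B = %d, %s, engine %s: %s)\n"),
    x$taxon, x$rank, length(x$leaves), x$r2_original, mean(x$r2_perm),
    x$p_value, x$b, x$tie_rule, x$engine,
    paste(x$metrics, collapse = "+")
  ))
  invisible(x)
}

#' Tidiers for CAT results
#'
#' `tidy()` returns one row per permuted dataset; `glance()` returns the
#' one-row summary used by [write_results()].
#'
#' @param x A `cat_result` (or other fitted object from this package).
#' @param ... Unused.
#' @name tidiers
NULL

#' @rdname tidiers
#' @export
tidy.cat_result <- function(x, ...) {
  tibble::tibble(
    taxon = x$taxon,
    permutation = seq_along(x$r2_perm),
    r2_perm = x$r2_perm
  )
}

#' @rdname tidiers
#' @export
glance.cat_result <- function(x, ...) {
  tibble::tibble(
    taxon = x$taxon, rank = x$rank, n_leaves = length(x$leaves),
    r2_original = x$r2_original, r2_perm_mean = mean(x$r2_perm),
    p_value = x$p_value, B = x$b,
    seed = x$seed %||% NA_integer_
  )
}

#' Run CAT over several taxa
#'
#' Applies [cat_test()] to each taxon with a shared outcome-side setup and
#' per-taxon RNG substreams derived from the master seed, so every row is
#' reproducible independently of evaluation order. Failures are recorded
#' per row (column `error`), not raised. P-values are unadjusted;
#' multiplicity control is left to the caller.
#'
#' @inheritParams cat_test
#' @param taxa Nonempty character vector of taxa to test.
#' @return A tibble with one row per taxon: `taxon`, `rank`, `n_leaves`,
#'   `r2_original`, `r2_perm_mean`, `p_value`, `B`, `seed`, `error`.
#' @export
cat_test_many <- function(table, taxonomy, tree = NULL, outcome, taxa,
                          metrics = "braycurtis",
                          engine = c("permanova", "mirkat"), b = 999,
                          seed = NULL,
                          tie_rule = c("add_one_tie_inclusive",
                                       "strict_paper"),
                          permute_mode = c("per_column", "joint"),
                          unifrac_normalized = FALSE) {
  engine <- arg_match(engine)
  tie_rule <- arg_match(tie_rule)
  permute_mode <- arg_match(permute_mode)
  if (length(taxa) == 0) abort("no taxa supplied")
  run_fun <- cat_setup(table, tree, outcome, metrics, engine,
                       unifrac_normalized)
  r2_original <- run_fun(table)
  purrr::map_dfr(taxa, function(tx) {
    res <- tryCatch(
      glance(cat_test_impl(table, taxonomy, tx, run_fun, b, seed,
                           tie_rule, permute_mode, engine, metrics,
                           r2_original = r2_original)),
      error = function(e) {
        tibble::tibble(
          taxon = tx, rank = NA_character_, n_leaves = NA_integer_,
          r2_original = NA_real_, r2_perm_mean = NA_real_,
          p_value = NA_real_, B = b, seed = seed %||% NA_integer_,
          error = conditionMessage(e)
        )
      }
    )
    if (!"error" %in% names(res)) res$error <- NA_character_
    res
  })
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
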