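#' Beta-diversity distance matrices
#'
#' All distance functions take a sample-by-feature [count_table] and return
#' a full symmetric `n x n` matrix with sample ids as dimnames, zero
#' diagonal and nonnegative finite entries. Bray-Curtis and Jaccard operate
#' on raw counts / presence; the UniFrac pair additionally uses a rooted
#' phylogenetic tree with branch lengths. No rarefaction is performed.
#'
#' @param table A [count_table].
#' @param tree An [ape::phylo] tree whose tips cover every feature of
#'   `table` that carries a nonzero count.
#' @param normalized For [unifrac_weighted()], divide each pairwise sum of
#'   branch-length-weighted proportion differences by the corresponding sum
#'   of proportions, bounding the distance in `[0, 1]`.
#' @return An `n x n` numeric distance matrix.
#' @name distances
NULL

check_positive_totals <- function(table) {
  tot <- rowSums(table)
  if (any(tot == 0)) {
    abort(sprintf("sample '%s' has zero total count",
                  rownames(table)[tot == 0][1]))
  }
  tot
}

as_distance_matrix <- function(d, ids) {
  m <- as.matrix(d)
  dimnames(m) <- list(ids, ids)
  m
}

#' @rdname distances
#' @export
bray_curtis <- function(table) {
  check_positive_totals(table)
  as_distance_matrix(vegan::vegdist(unclass(table), method = "bray"),
                     rownames(table))
}

#' @rdname distances
#' @export
jaccard <- function(table) {
  check_positive_totals(table)
  as_distance_matrix(
    vegan::vegdist(unclass(table), method = "jaccard", binary = TRUE),
    rownames(table)
  )
}

#' @rdname distances
#' @export
euclidean_dist <- function(table) {
  m <- as.matrix(table)
  if (!is.numeric(m)) abort("euclidean_dist needs a numeric table")
  as_distance_matrix(dist(m), rownames(m) %||% seq_len(nrow(m)))
}

# Precompute the branch structure UniFrac needs: for every edge, the set of
# count-table features descending through it, encoded as a feature x edge
# incidence matrix, plus branch lengths. CAT recomputes UniFrac B times per
# taxon, so this is built once per tree and reused.
unifrac_context <- function(tree, feature_ids, require_all = TRUE) {
  tree <- validate_phylo(tree)
  tips <- tree$tip.label
  missing <- setdiff(feature_ids, tips)
  if (require_all && length(missing)) {
    abort(sprintf("feature '%s' is missing from the phylogenetic tree",
                  missing[1]))
  }
  used <- intersect(feature_ids, tips)
  desc <- phangorn::Descendants(tree, tree$edge[, 2], type = "tips")
  nb <- nrow(tree$edge)
  inc <- matrix(0, length(used), nb,
                dimnames = list(used, NULL))
  tip_idx <- match(used, tips)
  for (e in seq_len(nb)) {
    hit <- match(desc[[e]], tip_idx)
    hit <- hit[!is.na(hit)]
    if (length(hit)) inc[hit, e] <- 1
  }
  list(incidence = inc, lengths = tree$edge.length, features = used)
}

# branch loads: n x edges matrix of per-sample mass descending each branch
branch_loads <- function(table, ctx, proportions = TRUE) {
  m <- as.matrix(table)[, ctx$features, drop = FALSE]
  storage.mode(m) <- "double"
  if (proportions) {
    tot <- check_positive_totals(table)
    m <- m / tot
  }
  m %*% ctx$incidence
}

unifrac_unweighted_impl <- function(table, ctx) {
  pres <- (branch_loads(table, ctx, proportions = FALSE) > 0) * 1
  presl <- sweep(pres, 2, ctx$lengths, `*`)
  shared <- tcrossprod(presl, pres)
  tot <- rowSums(presl)
  both <- outer(tot, tot, `+`)
  u <- both - 2 * shared  # branch length unique to one of the two samples
  un <- both - shared     # branch length spanned by either sample
  d <- ifelse(un > 0, u / un, 0)
  diag(d) <- 0
  as_distance_matrix((d + t(d)) / 2, rownames(table))
}

#' @rdname distances
#' @export
unifrac_unweighted <- function(table, tree) {
  check_positive_totals(table)
  ctx <- unifrac_context(tree, active_features(table))
  unifrac_unweighted_impl(table, ctx)
}

unifrac_weighted_impl <- function(table, ctx, normalized = FALSE) {
  loads <- branch_loads(table, ctx, proportions = TRUE)
  loadsl <- sweep(loads, 2, ctx$lengths, `*`)
  d <- as.matrix(dist(loadsl, method = "manhattan"))
  if (normalized) {
    tot <- rowSums(loadsl)
    denom <- outer(tot, tot, `+`)
    d <- ifelse(denom > 0, d / denom, 0)
    diag(d) <- 0
  }
  as_distance_matrix(d, rownames(table))
}

#' @rdname distances
#' @export
unifrac_weighted <- function(table, tree, normalized = FALSE) {
  ctx <- unifrac_context(tree, active_features(table))
  unifrac_weighted_impl(table, ctx, normalized)
}

# features carrying any count (the ones a UniFrac call must find in the tree)
active_features <- function(table) {
  colnames(table)[colSums(as.matrix(table)) > 0]
}

DISTANCE_METRICS <- c("braycurtis", "jaccard", "unifrac", "wunifrac",
                      "euclidean")

# A reusable metric closure: counts matrix in, distance matrix out, with the
# tree bookkeeping hoisted out of the permutation loop.
metric_function <- function(metric, table, tree = NULL,
                            unifrac_normalized = FALSE) {
  metric <- arg_match0(metric, DISTANCE_METRICS)
  if (metric %in% c("unifrac", "wunifrac")) {
    if (is.null(tree)) {
      abort(sprintf("metric '%s' requires a phylogenetic tree", metric))
    }
    # permutation shuffles counts within columns, so the active feature set
    # can only shrink; build the context over all features ever active
    ctx <- unifrac_context(tree, active_features(table))
    if (metric == "unifrac") {
      function(z) unifrac_unweighted_impl(z, ctx)
    } else {
      function(z) unifrac_weighted_impl(z, ctx, unifrac_normalized)
    }
  } else {
    switch(metric,
      braycurtis = bray_curtis,
      jaccard = jaccard,
      euclidean = euclidean_dist
    )
  }
}

#' Export a distance matrix as a square TSV
#'
#' @param d A distance matrix with sample ids as dimnames.
#' @param path Output path.
#' @export
write_distance <- function(d, path) {
  df <- tibble::as_tibble(as.data.frame(d), rownames = "sample_id")
  readr::write_tsv(df, path)
  invisible(path)
}
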