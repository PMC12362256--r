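#' Gower double-centering of a distance matrix
#'
#' Transforms squared distances into the inner-product-like matrix
#' `G = J (-D^2 / 2) J` with `J = I - 11'/n`. Its trace is the total sum of
#' squares that PERMANOVA partitions, and it is the kernel in the
#' MiRKAT-style score statistic.
#'
#' @param d An `n x n` distance matrix (`n >= 2`).
#' @return An `n x n` doubly centered symmetric matrix.
#' @export
gower_center <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 2 || ncol(d) != n) abort("need a square distance matrix, n >= 2")
  a <- -0.5 * d^2
  rm <- rowMeans(a)
  g <- a - rm - rep(rowMeans(t(a)), each = n) + mean(a)
  g <- (g + t(g)) / 2
  dimnames(g) <- dimnames(d)
  g
}

#' Build a full-rank design matrix from an outcome and covariates
#'
#' Encodes the grouping/outcome and optional covariates as an intercept
#' column, reference-coded dummies for factors, and raw numeric columns.
#' Linearly dependent columns are dropped with a warning so the projector
#' is always well defined.
#'
#' @param outcome An [outcome_spec], or a vector used directly as the
#'   variable of interest (factor/character become groups).
#' @param covariates Optional data frame of covariates; defaults to the
#'   covariates stored in an `outcome_spec`.
#' @param include_intercept Include the intercept column (default `TRUE`).
#' @return A numeric design matrix with attribute `"n_covariate_cols"`
#'   giving the number of non-intercept columns contributed by covariates
#'   (used for sequential sums of squares).
#' @export
build_design <- function(outcome, covariates = NULL,
                         include_intercept = TRUE) {
  if (inherits(outcome, "outcome_spec")) {
    covariates <- covariates %||% outcome$covariates
    if (outcome$kind == "survival") {
      abort("survival outcomes have no PERMANOVA design; use the mirkat engine")
    }
    v <- outcome$values
  } else {
    v <- outcome
  }
  if (is.character(v) || is.logical(v)) v <- factor(v)
  if (is.factor(v) && nlevels(droplevels(v)) < 2) {
    abort("outcome is constant: a single group cannot be tested")
  }
  if (is.numeric(v) && length(unique(v)) < 2) {
    abort("outcome is constant: nothing to test")
  }
  df <- data.frame(.outcome = v)
  cov_cols <- 0L
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    df <- cbind(covariates, df)
  }
  mm <- stats::model.matrix(~., data = df)
  if (!is.null(covariates)) {
    cov_cols <- ncol(stats::model.matrix(~., data = covariates)) - 1L
  }
  if (!include_intercept) mm <- mm[, -1, drop = FALSE]
  q <- qr(mm)
  if (q$rank < ncol(mm)) {
    drop <- q$pivot[(q$rank + 1):ncol(mm)]
    warn(paste("dropping linearly dependent design column(s):",
               paste(colnames(mm)[drop], collapse = ", ")))
    mm <- mm[, -drop, drop = FALSE]
  }
  attr(mm, "n_covariate_cols") <- cov_cols
  mm
}

# Orthogonal projector onto the column space of a design matrix, via QR;
# rank deficiency is handled by the QR pivoting (pseudo-inverse projector).
hat_matrix <- function(design) {
  q <- qr(design)
  qq <- qr.Q(q)[, seq_len(q$rank), drop = FALSE]
  tcrossprod(qq)
}

#' PERMANOVA sum-of-squares decomposition and R-squared
#'
#' Partitions the total sum of squares `tr(G)` of a Gower-centered matrix
#' into the part explained by a design (`tr(HG)`, with `H` the projector
#' onto the design's column space) and a residual, and reports
#' `R^2 = SS_A / SS_T`. Because `G` is doubly centered the intercept
#' contributes nothing to `tr(HG)`.
#'
#' @param g A Gower-centered matrix from [gower_center()].
#' @param design A design matrix from [build_design()].
#' @return A list of class `ss_decomposition` with elements `ss_total`,
#'   `ss_among`, `ss_residual`, `r2`, `df_among`, `df_residual`,
#'   `pseudo_f`.
#' @export
permanova_r2 <- function(g, design) {
  n <- nrow(g)
  if (nrow(design) != n) abort("design rows must equal the number of samples")
  h <- hat_matrix(design)
  ss_t <- sum(diag(g))
  ss_a <- sum(h * g)  # tr(HG) for symmetric H, G
  ss_r <- ss_t - ss_a
  # perfect separation leaves SS_R at rounding-error scale; clamp so the
  # pseudo-F is +Inf (and ties with equally perfect permutations) rather
  # than an arbitrary-signed huge ratio
  if (abs(ss_r) < 1e-12 * max(abs(ss_t), 1)) ss_r <- 0
  rank <- qr(design)$rank
  has_int <- any(apply(design, 2, function(x) all(x == x[1]) && x[1] != 0))
  df_a <- rank - as.integer(has_int)
  df_r <- n - rank
  structure(
    list(ss_total = ss_t, ss_among = ss_a, ss_residual = ss_r,
         r2 = ss_a / ss_t, df_among = df_a, df_residual = df_r,
         pseudo_f = if (df_a > 0 && df_r > 0) {
           (ss_a / df_a) / (ss_r / df_r)
         } else NA_real_),
    class = "ss_decomposition"
  )
}

#' @export
print.ss_decomposition <- function(x, ...) {
  cat(sprintf(
    "<ss_decomposition> SS_A %.4g + SS_R %.4g = SS_T %.4g; R2 = %.4f\n",
    x$ss_among, x$ss_residual, x$ss_total, x$r2
  ))
  invisible(x)
}

#' @rdname tidiers
#' @export
glance.ss_decomposition <- function(x, ...) {
  tibble::tibble(
    r2 = x$r2, ss_total = x$ss_total, ss_among = x$ss_among,
    ss_residual = x$ss_residual, pseudo_f = x$pseudo_f,
    df_among = x$df_among, df_residual = x$df_residual
  )
}

#' Partial (sequential) R-squared of the variable of interest
#'
#' The share of `tr(G)` explained by the full design beyond a nested
#' reduced design (covariates only): `(tr(H_full G) - tr(H_red G)) / tr(G)`.
#' With `design_reduced` the intercept-only design this reduces to plain
#' [permanova_r2()].
#'
#' @param g Gower-centered matrix.
#' @param design_full,design_reduced Design matrices; the reduced design's
#'   columns must be a subset of the full design's.
#' @return The sequential R-squared (a scalar).
#' @export
partial_r2 <- function(g, design_full, design_reduced) {
  nested <- all(apply(design_reduced, 2, function(col) {
    any(apply(design_full, 2, function(fc) isTRUE(all.equal(fc, col,
      check.attributes = FALSE))))
  }))
  if (!nested) abort("design_reduced must be nested in design_full")
  ss_t <- sum(diag(g))
  (sum(hat_matrix(design_full) * g) - sum(hat_matrix(design_reduced) * g)) /
    ss_t
}

#' PERMANOVA permutation p-value via the pseudo-F statistic
#'
#' Permutes sample labels (rows of the design) and compares the observed
#' pseudo-F to the permutation distribution, with the add-one correction
#' `p = (1 + #\{F_perm >= F_obs\}) / (n_perm + 1)`.
#'
#' @param d Distance matrix.
#' @param outcome Grouping vector or [outcome_spec].
#' @param covariates Optional covariate data frame.
#' @param n_perm Number of permutations (default 999).
#' @param seed Optional RNG seed for the permutations.
#' @return A list with `pseudo_f`, `p_value`, `r2`, `n_perm`.
#' @export
permanova_pvalue <- function(d, outcome, covariates = NULL, n_perm = 999,
                             seed = NULL) {
  if (n_perm < 1) abort("n_perm must be >= 1")
  g <- gower_center(d)
  design <- build_design(outcome, covariates)
  dec <- permanova_r2(g, design)
  if (dec$df_among < 1 || dec$df_residual < 1) {
    abort("degenerate degrees of freedom: check the design")
  }
  n <- nrow(g)
  run <- function() {
    f_perm <- vapply(seq_len(n_perm), function(b) {
      idx <- sample.int(n)
      permanova_r2(g[idx, idx], design)$pseudo_f
    }, numeric(1))
    (1 + sum(f_perm >= dec$pseudo_f)) / (n_perm + 1)
  }
  p <- if (is.null(seed)) run() else with_seed(seed, run())
  list(pseudo_f = dec$pseudo_f, p_value = p, r2 = dec$r2, n_perm = n_perm)
}

#' Principal coordinates analysis of a Gower-centered matrix
#'
#' Eigendecomposition of `G`; coordinates are eigenvectors scaled by the
#' square roots of the nonnegative eigenvalues. Axes with negative
#' eigenvalues (possible for semimetric distances) are reported but not
#' returned as coordinates.
#'
#' @param g Gower-centered matrix.
#' @param k Number of axes requested (`1 <= k <= n - 1`).
#' @return A list with `coordinates` (n x k', k' <= k), `eigenvalues`
#'   (all n), and `negative_eigenvalues`.
#' @export
pcoa <- function(g, k = 2) {
  n <- nrow(g)
  if (k < 1) abort("k must be >= 1")
  if (k > n - 1) abort("k must be <= n - 1")
  e <- eigen(g, symmetric = TRUE)
  tol <- max(abs(e$values), 1) * .Machine$double.eps * n
  pos <- which(e$values[seq_len(k)] >= -tol)
  coords <- e$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(pmax(e$values[pos], 0)), length(pos))
  rownames(coords) <- rownames(g)
  colnames(coords) <- paste0("PCo", seq_along(pos))
  list(
    coordinates = coords,
    eigenvalues = e$values,
    negative_eigenvalues = e$values[e$values < 0]
  )
}
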