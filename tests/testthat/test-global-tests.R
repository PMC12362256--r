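test_that("Gower centering matches the 2x2 closed form and centers rows", {
  d <- matrix(c(0, 3, 3, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  g <- gower_center(d)
  expect_equal(unname(g),
               matrix(c(9 / 4, -9 / 4, -9 / 4, 9 / 4), 2))
  expect_equal(sum(diag(g)), 9 / 2)

  z <- random_table(8, 5, seed = 2)
  g2 <- gower_center(bray_curtis(z))
  expect_true(all(abs(rowSums(g2)) < 1e-10))
  expect_true(all(abs(colSums(g2)) < 1e-10))
  expect_equal(gower_center(matrix(0, 3, 3)), matrix(0, 3, 3))
  expect_error(gower_center(matrix(0, 1, 1)), "n >= 2")
})

test_that("design matrices encode groups, factors and covariates", {
  d <- build_design(factor(c("A", "A", "B", "B")))
  expect_equal(unname(d), cbind(1, c(0, 0, 1, 1)),
               ignore_attr = TRUE)
  d3 <- build_design(factor(c("a", "b", "c", "a")))
  expect_identical(ncol(d3), 3L) # intercept + 2 dummies
  expect_warning(
    build_design(c(1, 2, 3, 4),
                 covariates = data.frame(u = c(1, 2, 3, 4))),
    "dependent"
  )
  expect_error(build_design(factor(c("A", "A"))), "single group")
  expect_error(build_design(rep(2, 4)), "constant")
})

test_that("PERMANOVA R2 on Euclidean distances equals one-way ANOVA R2", {
  # the worked example: perfect separation and the 0/1/2/3 case
  g1 <- gower_center(euclidean_dist(matrix(c(0, 0, 1, 1), 4, 1)))
  des <- build_design(factor(c("A", "A", "B", "B")))
  expect_equal(permanova_r2(g1, des)$r2, 1)

  dec <- permanova_r2(
    gower_center(euclidean_dist(matrix(c(0, 1, 2, 3), 4, 1))), des
  )
  expect_equal(dec$ss_total, 5)
  expect_equal(dec$ss_among, 4)
  expect_equal(dec$r2, 0.8)

  # analytic oracle on 50 random instances
  withr::with_seed(11, {
    for (i in 1:50) {
      n <- sample(6:20, 1)
      y <- rnorm(n)
      grp <- factor(sample(letters[1:sample(2:4, 1)], n, replace = TRUE))
      if (nlevels(droplevels(grp)) < 2) next
      dec <- permanova_r2(
        gower_center(euclidean_dist(matrix(y, n, 1))),
        build_design(grp)
      )
      fit <- summary(lm(y ~ grp))
      expect_equal(dec$r2, fit$r.squared, tolerance = 1e-10)
    }
  })
})

test_that("SS decomposition identity holds for every distance type", {
  z <- random_table(9, 12, seed = 4)
  withr::with_seed(5, {
    tr <- ape::rtree(12, br = rexp)
    tr$tip.label <- paste0("f", 1:12)
  })
  dists <- list(
    bray_curtis(z), jaccard(z), euclidean_dist(z),
    unifrac_unweighted(z, tr), unifrac_weighted(z, tr)
  )
  withr::with_seed(6, {
    for (d in dists) {
      g <- gower_center(d)
      grp <- factor(sample(c("A", "B", "C"), 9, replace = TRUE))
      if (nlevels(droplevels(grp)) < 2) grp <- factor(rep(c("A", "B"), c(4, 5)))
      dec <- permanova_r2(g, build_design(grp))
      expect_equal(dec$ss_among + dec$ss_residual, dec$ss_total,
                   tolerance = 1e-8)
      expect_equal(dec$r2, dec$ss_among / dec$ss_total)
    }
  })
})

test_that("PERMANOVA agrees with the vegan reference implementation", {
  z <- random_table(10, 8, seed = 21)
  grp <- factor(rep(c("A", "B"), 5))
  dec <- permanova_r2(gower_center(bray_curtis(z)), build_design(grp))
  ref <- vegan::adonis2(vegan::vegdist(unclass(z), "bray") ~ grp,
                        permutations = 2)
  expect_equal(dec$r2, ref$R2[1], tolerance = 1e-10)
  expect_equal(dec$pseudo_f, ref$F[1], tolerance = 1e-10)
})

test_that("partial R2 is sequential and nests correctly", {
  withr::with_seed(31, {
    z <- random_table(12, 6)
    g <- gower_center(bray_curtis(z))
    grp <- factor(rep(c("A", "B"), 6))
    cov <- data.frame(u = rnorm(12))
    full <- build_design(grp, covariates = cov)
    red <- build_design(grp)[, 1, drop = FALSE] # intercept only
    red_cov <- stats::model.matrix(~u, data = cov)
    # reduced = intercept only: equals plain R2 of the grouping design
    expect_equal(partial_r2(g, build_design(grp), red),
                 permanova_r2(g, build_design(grp))$r2)
    # full = reduced: exactly zero
    expect_equal(partial_r2(g, full, full), 0)
    # sequential share is bounded by the full-model R2
    pr <- partial_r2(g, full, red_cov)
    expect_lte(pr, permanova_r2(g, full)$r2 + 1e-12)
    expect_error(
      partial_r2(g, red_cov, build_design(grp)),
      "nested"
    )
  })
})

test_that("pseudo-F permutation p-values behave at the extremes and null", {
  # perfect separation: only the rare group-preserving relabelings tie
  # with the observed F, so p sits near its attainable minimum
  z <- matrix(rep(c(0, 1), each = 5), 10, 1)
  grp <- factor(rep(c("A", "B"), each = 5))
  res <- permanova_pvalue(euclidean_dist(z), grp, n_perm = 199, seed = 1)
  expect_lt(res$p_value, 0.05)
  expect_error(permanova_pvalue(euclidean_dist(z), factor(rep("A", 10))),
               "single group")

  # type-I error within the binomial band at alpha = 0.05
  reps <- 400
  rej <- withr::with_seed(99, vapply(seq_len(reps), function(i) {
    y <- matrix(rnorm(14), 14, 1)
    grp <- factor(rep(c("A", "B"), 7))
    permanova_pvalue(euclidean_dist(y), grp, n_perm = 99)$p_value < 0.05
  }, logical(1)))
  band <- 0.05 + c(-1, 1) * 1.96 * sqrt(0.05 * 0.95 / reps)
  expect_gte(mean(rej), band[1])
  expect_lte(mean(rej), band[2])
})

test_that("kernel score matches brute-force quadratic forms", {
  # explicit 3x3 expansion
  g <- gower_center(euclidean_dist(matrix(c(0, 1, 2), 3, 1)))
  r <- c(1, -1, 0)
  brute <- 0
  for (i in 1:3) for (j in 1:3) brute <- brute + r[i] * g[i, j] * r[j]
  ks <- mirkat_q(r, phi = 2, g)
  expect_equal(ks$q, brute / 4)
  expect_equal(ks$r2_kernel, brute / (sum(diag(g)) * 2))

  # random instances at n <= 6
  withr::with_seed(13, {
    for (rep in 1:25) {
      ni <- sample(3:6, 1)
      zi <- random_table(ni, 4)
      gi <- gower_center(bray_curtis(zi))
      ri <- rnorm(ni)
      brute_i <- sum(outer(ri, ri) * gi)
      expect_equal(mirkat_q(ri, 1, gi)$q, brute_i / 2, tolerance = 1e-10)
    }
  })

  # homogeneity: doubling r quadruples q, leaves r2_kernel unchanged
  ks2 <- mirkat_q(2 * r, phi = 2, g)
  expect_equal(ks2$q, 4 * ks$q)
  expect_equal(ks2$r2_kernel, ks$r2_kernel)
  # scaling all distances leaves r2_kernel unchanged
  gs <- gower_center(3 * euclidean_dist(matrix(c(0, 1, 2), 3, 1)))
  expect_equal(mirkat_q(r, 1, gs)$r2_kernel, mirkat_q(r, 1, g)$r2_kernel)
  expect_error(mirkat_q(rep(0, 3), 1, g), "zero")
})

test_that("null fits produce the documented residual structure", {
  withr::with_seed(17, {
    y <- rnorm(20)
    fit <- mirkat_null_fit(outcome_spec("continuous", y))
    expect_equal(fit$residuals, y - mean(y))
    expect_equal(fit$phi, var(y))

    x <- rbinom(20, 1, 0.4)
    fitb <- mirkat_null_fit(outcome_spec("binary", x))
    expect_equal(fitb$residuals, x - mean(x), tolerance = 1e-6)
    expect_identical(fitb$phi, 1)

    times <- rexp(20) + 0.01
    fits <- mirkat_null_fit(
      outcome_spec("survival", times, event = rep(1, 20))
    )
    expect_equal(sum(fits$residuals), 0, tolerance = 1e-8)
  })
  expect_error(
    mirkat_null_fit(outcome_spec("categorical", c("a", "b", "c", "a"))),
    "continuous, binary or survival"
  )
})

test_that("max over metrics picks the largest R2", {
  expect_equal(max_over_metrics(0.1), 0.1)
  expect_equal(max_over_metrics(c(0.1, 0.3, 0.2)), 0.3)
  expect_equal(max_over_metrics(c(0.2, 0.2)), 0.2)
  expect_error(max_over_metrics(numeric(0)), "no R-squared")
})

test_that("PCoA recovers Euclidean configurations and degenerate cases", {
  withr::with_seed(23, {
    pts <- matrix(rnorm(20), 10, 2)
  })
  res <- pcoa(gower_center(euclidean_dist(pts)), k = 2)
  # Procrustes: compare against cmdscale (classical MDS exactness)
  ref <- stats::cmdscale(dist(pts), k = 2)
  pro <- vegan::procrustes(ref, res$coordinates, symmetric = TRUE)
  expect_lt(pro$ss, 1e-8)
  pro0 <- vegan::procrustes(pts, res$coordinates, symmetric = TRUE)
  expect_lt(pro0$ss, 1e-8)

  # 2 samples at distance d: coordinates +/- d/2
  d <- matrix(c(0, 3, 3, 0), 2)
  res2 <- pcoa(gower_center(d), k = 1)
  expect_setequal(round(res2$coordinates[, 1], 10), c(1.5, -1.5))

  res0 <- pcoa(gower_center(matrix(0, 3, 3)), k = 2)
  expect_true(all(res0$coordinates == 0))
  expect_error(pcoa(gower_center(d), k = 0), "k must be >= 1")
})
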