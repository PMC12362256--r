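test_that("taxon permutation preserves column multisets and the rest", {
  withr::with_seed(41, {
    for (rep in 1:20) {
      n <- sample(4:12, 1)
      m <- sample(4:10, 1)
      z <- random_table(n, m)
      sel <- sample(colnames(z), sample(seq_len(m - 1), 1))
      mode <- sample(c("per_column", "joint"), 1)
      zp <- permute_taxon(z, sel, mode = mode)
      # selected columns: same multiset of values
      for (s in sel) expect_equal(sort(zp[, s]), sort(z[, s]))
      expect_equal(colSums(zp), colSums(z))
      # unselected columns bit-identical
      rest <- setdiff(colnames(z), sel)
      expect_identical(zp[, rest, drop = FALSE], z[, rest, drop = FALSE])
      if (mode == "joint") {
        # one shared row permutation: within-block rows stay intact
        blk <- z[, sel, drop = FALSE]
        blk_p <- zp[, sel, drop = FALSE]
        key <- unname(apply(blk, 1, paste, collapse = ","))
        key_p <- unname(apply(blk_p, 1, paste, collapse = ","))
        expect_setequal(key_p, key)
      }
    }
  })
  z <- random_table(5, 3, seed = 1)
  expect_error(permute_taxon(z, character(0)), "empty")
  expect_error(permute_taxon(z, "nope"), "not a column")
  # constant selected column is unchanged for every draw
  zc <- count_table(cbind(unclass(z), const = 4L))
  expect_identical(permute_taxon(zc, "const")[, "const"], zc[, "const"])
})

test_that("empirical p-values follow the tie rules", {
  expect_equal(
    empirical_pvalue(0.5, c(0.4, 0.6, 0.45), "strict_paper"), 1 / 3
  )
  expect_equal(
    empirical_pvalue(0.5, c(0.4, 0.6, 0.45), "add_one_tie_inclusive"), 0.5
  )
  # tie saturation: permutation leaves R2 unchanged
  expect_equal(empirical_pvalue(0.3, rep(0.3, 10), "strict_paper"), 0)
  expect_equal(empirical_pvalue(0.3, rep(0.3, 10), "add_one_tie_inclusive"),
               1)
  # everything above the observed value
  expect_equal(empirical_pvalue(0.1, rep(0.2, 5), "strict_paper"), 1)
  expect_equal(empirical_pvalue(0.1, rep(0.2, 5), "add_one_tie_inclusive"),
               1)
  expect_error(empirical_pvalue(0.5, numeric(0)), "no permuted")
})

make_degenerate_fixture <- function() {
  # family DegFam's two leaves are constant across samples, so permuting
  # them can never change any distance matrix
  n <- 12
  withr::with_seed(3, {
    z <- cbind(
      d1 = rep(3L, n), d2 = rep(1L, n),
      o1 = rpois(n, 30), o2 = rpois(n, 30)
    )
  })
  rownames(z) <- paste0("s", seq_len(n))
  tax <- build_taxonomy(tibble::tibble(
    feature = colnames(z),
    lineage = c(
      "k__K; p__P1; c__C1; o__O1; f__DegFam; g__G1; s__S1",
      "k__K; p__P1; c__C1; o__O1; f__DegFam; g__G2; s__S2",
      "k__K; p__P2; c__C2; o__O2; f__Other; g__G3; s__S3",
      "k__K; p__P2; c__C2; o__O2; f__Other; g__G4; s__S4"
    )
  ))
  list(table = count_table(z), taxonomy = tax,
       group = rep(c(0, 1), n / 2))
}

test_that("a degenerate (constant-column) taxon saturates the tie rules", {
  fx <- make_degenerate_fixture()
  res <- cat_test(fx$table, fx$taxonomy, NULL,
                  outcome_spec("binary", fx$group), "DegFam",
                  metrics = "braycurtis", b = 49, seed = 5)
  expect_equal(res$p_value, 1)
  expect_true(all(res$r2_perm == res$r2_original))
  res_strict <- cat_test(fx$table, fx$taxonomy, NULL,
                         outcome_spec("binary", fx$group), "DegFam",
                         metrics = "braycurtis", b = 49, seed = 5,
                         tie_rule = "strict_paper")
  expect_equal(res_strict$p_value, 0)
})

test_that("CAT results are reproducible and order-independent", {
  sim <- simulate_dataset(m = 30, n_per_group = 8, depth = 400, seed = 2)
  out <- outcome_spec("binary", sim$group)
  fams <- taxa_at_rank(sim$taxonomy, "family")
  fams <- fams$taxon[fams$n_leaves >= 2][1:2]
  taxa <- paste0("f__", fams)

  r1 <- cat_test_many(sim$table, sim$taxonomy, sim$tree, out, taxa,
                      metrics = "braycurtis", b = 29, seed = 11)
  r2 <- cat_test_many(sim$table, sim$taxonomy, sim$tree, out, rev(taxa),
                      metrics = "braycurtis", b = 29, seed = 11)
  expect_equal(r1[order(r1$taxon), ], r2[order(r2$taxon), ])
  # same taxon twice in one call gives identical rows
  r3 <- cat_test_many(sim$table, sim$taxonomy, sim$tree, out,
                      c(taxa[1], taxa[1]), metrics = "braycurtis",
                      b = 29, seed = 11)
  expect_equal(r3[1, ], r3[2, ])
  # unknown taxon fails row-wise, not fatally
  r4 <- cat_test_many(sim$table, sim$taxonomy, sim$tree, out,
                      c(taxa[1], "no_such_taxon"), metrics = "braycurtis",
                      b = 9, seed = 11)
  expect_true(is.na(r4$p_value[2]) && !is.na(r4$error[2]))
  expect_true(is.na(r4$error[1]))
  expect_equal(r4$r2_original[1], r1$r2_original[1])
})

test_that("CAT separates a driving family from its correlated shadow", {
  # family B drives the group difference; family A is a noisy thinned
  # shadow of B (marginally associated, conditionally redundant). CAT
  # should reject B but stay near the null for A, because the community
  # already explains the separation once B is in place.
  n <- 30
  grp <- rep(c(0L, 1L), each = n / 2)
  withr::with_seed(1, {
    big <- rpois(n, 200) + 150L * grp
    small <- rbinom(n, big, 0.02) + rpois(n, 60)
    noise <- matrix(rpois(8 * n, 100), n, 8)
  })
  z <- cbind(a1 = small, b1 = big, noise)
  colnames(z) <- c("a1", "b1", paste0("c", 1:8))
  rownames(z) <- paste0("s", seq_len(n))
  z <- count_table(z)
  tax <- build_taxonomy(tibble::tibble(
    feature = colnames(z),
    lineage = c(
      "k__K; p__P; c__C; o__O; f__FamA; g__GA",
      "k__K; p__P; c__C; o__O; f__FamB; g__GB",
      paste0("k__K; p__P2; c__C2; o__O2; f__FamC; g__GN", 1:8)
    )
  ))
  out <- outcome_spec("binary", grp)

  driver <- cat_test(z, tax, NULL, out, "f__FamB",
                     metrics = "braycurtis", b = 99, seed = 19)
  shadow <- cat_test(z, tax, NULL, out, "f__FamA",
                     metrics = "braycurtis", b = 99, seed = 19)
  expect_lt(driver$p_value, 0.05)
  expect_gt(shadow$p_value, 0.2)
  # signal response: permuted R2 drops below the original for the driver
  expect_gt(driver$r2_original, mean(driver$r2_perm))
})

test_that("engines validate outcome compatibility", {
  fx <- make_degenerate_fixture()
  surv <- outcome_spec("survival", values = rexp(12) + 0.1,
                       event = rep(1, 12))
  expect_error(
    cat_test(fx$table, fx$taxonomy, NULL, surv, "DegFam",
             metrics = "braycurtis", engine = "permanova", b = 9),
    "mirkat"
  )
  expect_error(
    cat_test(fx$table, fx$taxonomy, NULL,
             outcome_spec("categorical", rep(c("a", "b", "c"), 4)),
             "DegFam", metrics = "braycurtis", engine = "mirkat", b = 9),
    "continuous, binary or survival"
  )
  # survival + mirkat runs end to end
  res <- cat_test(fx$table, fx$taxonomy, NULL, surv, "Other",
                  metrics = "braycurtis", engine = "mirkat", b = 19,
                  seed = 2)
  expect_true(res$p_value > 0 && res$p_value <= 1)
})

test_that("tidiers and plots expose the result contract", {
  fx <- make_degenerate_fixture()
  res <- cat_test(fx$table, fx$taxonomy, NULL,
                  outcome_spec("binary", fx$group), "Other",
                  metrics = "braycurtis", b = 19, seed = 3)
  td <- tidy(res)
  expect_identical(nrow(td), 19L)
  gl <- glance(res)
  expect_named(gl, c("taxon", "rank", "n_leaves", "r2_original",
                     "r2_perm_mean", "p_value", "B", "seed"))
  expect_identical(gl$n_leaves, 2L)
  expect_s3_class(ggplot2::autoplot(res), "ggplot")
  d <- bray_curtis(fx$table)
  expect_s3_class(plot_pcoa(d, fx$group), "ggplot")
})
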