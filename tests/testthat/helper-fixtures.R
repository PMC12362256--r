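# Small fixtures built in code; nothing is read from disk except through
# tempfiles written by the tests themselves.

tiny_table <- function() {
  count_table(matrix(
    c(5L, 1L, 0L, 3L), 2,
    dimnames = list(c("s1", "s2"), c("f1", "f2"))
  ))
}

# random count table with positive row sums
random_table <- function(n, m, max_count = 20, seed = NULL) {
  draw <- function() {
    z <- matrix(rbinom(n * m, max_count, 0.4), n, m)
    z[rowSums(z) == 0, 1] <- 1L
    count_table(z,
      sample_ids = paste0("s", seq_len(n)),
      feature_ids = paste0("f", seq_len(m))
    )
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

two_leaf_tree <- function() ape::read.tree(text = "(A:1,B:1):0;")

demo_lineages <- function() {
  tibble::tibble(
    feature = c("f1", "f2", "f3", "f4"),
    lineage = c(
      "k__B; p__F; c__C1; o__O1; f__Fam1; g__G1; s__S1",
      "k__B; p__F; c__C1; o__O1; f__Fam1; g__G2; s__S2",
      "k__B; p__F; c__C2; o__O2; f__Fam2",
      "k__B; p__P2; c__C3"
    )
  )
}

demo_taxonomy <- function() build_taxonomy(demo_lineages())
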