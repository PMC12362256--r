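#' Synthetic phylogeny and taxonomy
#'
#' Draws a random rooted bifurcating tree with exponential(1) branch
#' lengths and derives a full seven-rank taxonomy from it by cutting the
#' tree at nested depth thresholds: the clade a leaf belongs to at rank r
#' is the first ancestor whose root distance crosses the rank's threshold,
#' so clades are nested and every leaf carries a complete
#' kingdom-to-species lineage.
#'
#' @param m Number of leaves (>= 2).
#' @param seed Optional RNG seed (fixed seed gives an identical tree).
#' @return A list with `tree` ([ape::phylo], tips `asv1..asvm`),
#'   `taxonomy` ([taxonomy]), and `lineages` (the generated lineage
#'   tibble).
#' @export
make_synthetic_tree <- function(m, seed = NULL) {
  if (m < 2) abort("need m >= 2 leaves")
  build <- function() {
    tree <- ape::rtree(m, rooted = TRUE, br = rexp)
    tree$tip.label <- paste0("asv", seq_len(m))
    tree
  }
  tree <- if (is.null(seed)) build() else with_seed(seed, build())

  depth <- ape::node.depth.edgelength(tree)
  parent <- integer(m + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  root <- m + 1L
  # thresholds for phylum..species: nested quantiles of the internal-node
  # depths (root excluded), chosen so the rank ladder has realistically
  # sized clades (a handful of phyla, a few dozen families for m ~ 200)
  internal <- depth[setdiff((m + 1L):(m + tree$Nnode), root)]
  taus <- cummax(quantile(internal, names = FALSE,
                          probs = c(0.02, 0.05, 0.10, 0.20, 0.40, 0.65)))

  # for each leaf, the root-to-leaf node path; clade at rank r = first node
  # with depth >= tau_r (the leaf itself if no internal node qualifies)
  rank_codes <- c("p", "c", "o", "f", "g", "s")
  clade_of <- matrix(NA_integer_, m, 6)
  for (tip in seq_len(m)) {
    path <- tip
    v <- tip
    while (v != root) {
      v <- parent[v]
      path <- c(v, path)
    }
    for (r in seq_len(6)) {
      hit <- which(depth[path] >= taus[r])[1]
      clade_of[tip, r] <- if (is.na(hit)) tip else path[hit]
    }
  }
  lineage <- vapply(seq_len(m), function(tip) {
    segs <- vapply(seq_len(6), function(r) {
      sprintf("%s__%s%03d", rank_codes[r], toupper(rank_codes[r]),
              clade_of[tip, r])
    }, character(1))
    paste(c("k__K1", segs), collapse = "; ")
  }, character(1))

  lineages <- tibble::tibble(feature = tree$tip.label, lineage = lineage)
  list(tree = tree, taxonomy = build_taxonomy(lineages),
       lineages = lineages)
}

#' Skewed base composition on the simplex
#'
#' Draws log-normal masses for the m leaves and normalizes them, giving
#' the highly skewed abundance profiles typical of gut microbiome family
#' distributions (a dominant family and a long tail of rare ones). The
#' achieved skew is reported — top family share and median family share
#' when a taxonomy is supplied — so a caller can pick `skew_sigma` to
#' approximate a desired profile.
#'
#' @param m Number of leaves.
#' @param skew_sigma Log-normal scale (> 0); larger is more skewed.
#' @param seed Optional RNG seed.
#' @param taxonomy Optional [taxonomy]; enables family-level summaries and
#'   names the proportions by its leaves.
#' @return A list with `proportions` (sums to 1) and `summary` (tibble
#'   with top/median shares at leaf and, if available, family level).
#' @export
make_base_composition <- function(m, skew_sigma = 3.5, seed = NULL,
                                  taxonomy = NULL) {
  if (m < 2) abort("need m >= 2 leaves")
  if (skew_sigma <= 0) abort("skew_sigma must be > 0")
  draw <- function() exp(rnorm(m, 0, skew_sigma))
  mass <- if (is.null(seed)) draw() else with_seed(seed, draw())
  p <- mass / sum(mass)
  summary <- tibble::tibble(
    level = "leaf", top_share = max(p), median_share = median(p)
  )
  if (!is.null(taxonomy)) {
    leaves <- taxonomy_leaves(taxonomy)
    if (length(leaves) != m) {
      abort("taxonomy leaf count does not match m")
    }
    names(p) <- leaves
    fam <- family_shares(taxonomy, p)
    summary <- dplyr::bind_rows(summary, tibble::tibble(
      level = "family", top_share = max(fam$share),
      median_share = median(fam$share)
    ))
  }
  list(proportions = p, summary = summary)
}

# per-family total share of a leaf-level composition
family_shares <- function(taxonomy, proportions) {
  fams <- taxa_at_rank(taxonomy, "family")
  fams$share <- vapply(fams$taxon, function(f) {
    sum(proportions[leaf_descendants(taxonomy, paste0("f__", f))])
  }, numeric(1))
  fams
}

#' Simulation configuration
#'
#' Bundles the study conditions for the Dirichlet-multinomial spike-in
#' generator. The defaults are the conditions of the two-group microbiome
#' study the generator emulates: 31 samples per group, sequencing depth
#' 48,765 reads per sample, and Dirichlet concentration parameters summing
#' to 62 (strong sample-to-sample overdispersion).
#'
#' @param base_proportions Length-m simplex vector of expected leaf
#'   abundances (see [make_base_composition()]).
#' @param n_per_group Samples per group (two groups).
#' @param depth Sequences per sample.
#' @param theta Dirichlet concentration sum (> 0).
#' @param spiked_taxon Taxon whose leaf ASVs receive the Poisson spike in
#'   group 1, or `NULL` for the null scenario.
#' @param lambda Poisson spike mean (>= 0).
#' @param spike_mode `"per_asv"`: an independent Poisson draw per spiked
#'   ASV per sample (default); `"shared_draw"`: one draw per sample added
#'   to every spiked ASV.
#' @param seed Optional RNG seed.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(base_proportions, n_per_group = 31,
                              depth = 48765, theta = 62,
                              spiked_taxon = NULL, lambda = 0,
                              spike_mode = c("per_asv", "shared_draw"),
                              seed = NULL) {
  spike_mode <- arg_match(spike_mode)
  if (abs(sum(base_proportions) - 1) > 1e-12 || any(base_proportions < 0)) {
    abort("base_proportions must be nonnegative and sum to 1 (tol 1e-12)")
  }
  if (n_per_group < 1 || depth < 1) abort("n_per_group and depth must be >= 1")
  if (theta <= 0) abort("theta must be > 0")
  if (lambda < 0) abort("lambda must be >= 0")
  structure(
    list(base_proportions = base_proportions, n_per_group = n_per_group,
         depth = depth, theta = theta, spiked_taxon = spiked_taxon,
         lambda = lambda, spike_mode = spike_mode, seed = seed),
    class = "simulation_config"
  )
}

#' Dirichlet-multinomial counts with a Poisson spike-in
#'
#' For each of the 2 x `n_per_group` samples, draws a composition from
#' `Dirichlet(theta * base_proportions)` and counts from
#' `Multinomial(depth, p)`. For group-1 samples, adds Poisson(`lambda`)
#' counts to each leaf ASV of the spiked taxon, constructing a group
#' difference concentrated on that clade. Group-0 totals equal `depth`
#' exactly; group-1 totals exceed it by exactly the spike mass.
#'
#' @param config A [simulation_config()].
#' @param taxonomy A [taxonomy] whose leaves name the features (required
#'   when `spiked_taxon` is set; also used to name columns).
#' @return A list with `table` ([count_table]), `group` (0/1 vector) and
#'   `spike_total` (per-sample added counts).
#' @export
simulate_counts <- function(config, taxonomy = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  m <- length(config$base_proportions)
  feats <- names(config$base_proportions) %||%
    (if (!is.null(taxonomy)) taxonomy_leaves(taxonomy)) %||%
    paste0("asv", seq_len(m))
  n <- 2L * config$n_per_group
  group <- rep(c(0L, 1L), each = config$n_per_group)
  spike_cols <- NULL
  if (!is.null(config$spiked_taxon)) {
    if (is.null(taxonomy)) abort("spiked_taxon requires a taxonomy")
    leaves <- leaf_descendants(taxonomy, config$spiked_taxon)
    if (length(leaves) == 0) abort("spiked taxon has no leaves")
    spike_cols <- match(leaves, feats)
    if (anyNA(spike_cols)) abort("spiked taxon leaves not in base composition")
  }
  draw <- function() {
    alpha <- config$theta * config$base_proportions
    z <- matrix(0L, n, m)
    spike_total <- numeric(n)
    for (i in seq_len(n)) {
      gam <- rgamma(m, shape = alpha, rate = 1)
      if (sum(gam) == 0) gam <- rep(1, m) # pathological underflow guard
      z[i, ] <- rmultinom(1, config$depth, gam / sum(gam))
    }
    if (!is.null(spike_cols) && config$lambda > 0) {
      for (i in which(group == 1L)) {
        add <- if (config$spike_mode == "per_asv") {
          rpois(length(spike_cols), config$lambda)
        } else {
          rep(rpois(1, config$lambda), length(spike_cols))
        }
        z[i, spike_cols] <- z[i, spike_cols] + add
        spike_total[i] <- sum(add)
      }
    }
    list(z = z, spike_total = spike_total)
  }
  out <- if (is.null(config$seed)) draw() else with_seed(config$seed, draw())
  table <- count_table(out$z,
                       sample_ids = sprintf("g%d_s%02d", group, seq_len(n)),
                       feature_ids = feats)
  list(table = table, group = group, spike_total = out$spike_total)
}

#' One-call synthetic dataset
#'
#' Convenience wrapper drawing a synthetic tree/taxonomy, a skewed base
#' composition, and a Dirichlet-multinomial count table in one step, with
#' sub-seeds derived from one master seed.
#'
#' @inheritParams simulation_config
#' @param m Number of leaf features.
#' @param skew_sigma Log-normal skew of the base composition.
#' @param seed Master seed.
#' @return A list with `table`, `group`, `taxonomy`, `tree`,
#'   `base_proportions`, `config`.
#' @export
simulate_dataset <- function(m = 200, n_per_group = 31, depth = 48765,
                             theta = 62, skew_sigma = 3.5,
                             spiked_taxon = NULL, lambda = 0,
                             spike_mode = "per_asv", seed = NULL) {
  syn <- make_synthetic_tree(m, seed = if (!is.null(seed)) {
    derive_seed(seed, "tree")
  })
  comp <- make_base_composition(m, skew_sigma,
                                seed = if (!is.null(seed)) {
                                  derive_seed(seed, "composition")
                                }, taxonomy = syn$taxonomy)
  config <- simulation_config(
    comp$proportions, n_per_group = n_per_group, depth = depth,
    theta = theta, spiked_taxon = spiked_taxon, lambda = lambda,
    spike_mode = spike_mode,
    seed = if (!is.null(seed)) derive_seed(seed, "counts")
  )
  sim <- simulate_counts(config, syn$taxonomy)
  c(sim, list(taxonomy = syn$taxonomy, tree = syn$tree,
              lineages = syn$lineages,
              base_proportions = comp$proportions, config = config))
}

#' Pick a mid-size family from a base composition
#'
#' Returns the family whose total expected abundance is closest to
#' `target_share` — the "moderately abundant" clade a spike-in power study
#' targets. Ties break toward more leaves, then name order.
#'
#' @param taxonomy A [taxonomy].
#' @param proportions Leaf-level base composition named by feature.
#' @param target_share Desired family share (default 0.03).
#' @param min_leaves Require at least this many leaf ASVs (default 2).
#' @return The family name (unqualified).
#' @export
pick_family <- function(taxonomy, proportions, target_share = 0.03,
                        min_leaves = 2) {
  fams <- family_shares(taxonomy, proportions)
  fams <- fams[fams$n_leaves >= min_leaves, ]
  if (nrow(fams) == 0) abort("no family with enough leaves")
  fams <- fams[order(abs(fams$share - target_share), -fams$n_leaves,
                     fams$taxon), ]
  fams$taxon[1]
}

#' Type-I error / power study for CAT
#'
#' Runs the full simulation-to-test pipeline over a grid of spike
#' strengths: one synthetic ecosystem (tree, taxonomy, base composition)
#' is fixed per study, fresh Dirichlet-multinomial counts are drawn per
#' dataset, the chosen family is spiked at each `lambda` (0 = null), and
#' CAT is run on it. Reports per-lambda rejection rates at `alpha` with
#' binomial standard errors, plus the per-dataset R-squared and p-value
#' streams.
#'
#' @param lambda_values Spike means; 0 rows measure type-I error.
#' @param n_datasets Datasets per lambda.
#' @param taxa Taxon (family) to spike and test; `NULL` picks the family
#'   whose expected share is nearest `target_share` via [pick_family()].
#' @param m,n_per_group,depth,theta,skew_sigma Generator settings (see
#'   [simulate_dataset()]).
#' @param metrics,engine,b,tie_rule,permute_mode CAT settings.
#' @param alpha Rejection threshold (default 0.05).
#' @param target_share Family-share target for automatic taxon choice.
#' @param seed Master seed; every dataset gets a derived substream.
#' @return A list with `rates` (tibble: lambda, taxon, n_datasets,
#'   rejections, rejection_rate, se) and `detail` (tibble: lambda,
#'   dataset, taxon, r2_original, r2_perm_mean, p_value).
#' @export
run_calibration_study <- function(lambda_values = c(0, 10, 70),
                                  n_datasets = 20, taxa = NULL, m = 200,
                                  n_per_group = 31, depth = 48765,
                                  theta = 62, skew_sigma = 3.5,
                                  metrics = "wunifrac",
                                  engine = "permanova", b = 99,
                                  tie_rule = "add_one_tie_inclusive",
                                  permute_mode = "per_column",
                                  alpha = 0.05, target_share = 0.03,
                                  seed = 1) {
  if (n_datasets < 1) abort("n_datasets must be >= 1")
  syn <- make_synthetic_tree(m, seed = derive_seed(seed, "tree"))
  comp <- make_base_composition(m, skew_sigma,
                                seed = derive_seed(seed, "composition"),
                                taxonomy = syn$taxonomy)
  family <- taxa %||% pick_family(syn$taxonomy, comp$proportions,
                                  target_share)
  taxon_ref <- if (grepl("__|:", family)) family else paste0("f__", family)

  detail <- purrr::map_dfr(lambda_values, function(lam) {
    purrr::map_dfr(seq_len(n_datasets), function(i) {
      config <- simulation_config(
        comp$proportions, n_per_group = n_per_group, depth = depth,
        theta = theta,
        spiked_taxon = if (lam > 0) taxon_ref,
        lambda = lam,
        seed = derive_seed(seed, sprintf("counts|%g|%d", lam, i))
      )
      sim <- simulate_counts(config, syn$taxonomy)
      res <- tryCatch(
        glance(cat_test(
          sim$table, syn$taxonomy, syn$tree,
          outcome_spec("binary", sim$group), taxon = taxon_ref,
          metrics = metrics, engine = engine, b = b,
          seed = derive_seed(seed, sprintf("cat|%g|%d", lam, i)),
          tie_rule = tie_rule, permute_mode = permute_mode
        )),
        error = function(e) {
          tibble::tibble(r2_original = NA_real_, r2_perm_mean = NA_real_,
                         p_value = NA_real_, error = conditionMessage(e))
        }
      )
      tibble::tibble(
        lambda = lam, dataset = i, taxon = family,
        r2_original = res$r2_original, r2_perm_mean = res$r2_perm_mean,
        p_value = res$p_value,
        error = if ("error" %in% names(res)) res$error else NA_character_
      )
    })
  })

  rates <- detail |>
    dplyr::filter(!is.na(.data$p_value)) |>
    dplyr::group_by(.data$lambda, .data$taxon) |>
    dplyr::summarise(
      n_datasets = dplyr::n(),
      rejections = sum(.data$p_value < alpha),
      rejection_rate = mean(.data$p_value < alpha),
      se = sqrt(.data$rejection_rate * (1 - .data$rejection_rate) /
                  dplyr::n()),
      .groups = "drop"
    )
  list(rates = rates, detail = detail, family = family)
}

#' Synthetic survival outcome tied to a taxon's abundance
#'
#' Generates exponential event times whose log-hazard is linear in the
#' (standardized) relative abundance of an optional effect taxon, with
#' independent uniform censoring calibrated to an approximate target
#' censoring rate. With `effect_size = 0` the times are independent of the
#' microbiome — the null construction for calibrating the survival engine.
#'
#' @param table A [count_table].
#' @param taxonomy A [taxonomy] (required when `effect_taxon` is set).
#' @param effect_taxon Optional taxon driving the hazard.
#' @param effect_size Log-hazard slope per SD of relative abundance.
#' @param censor_rate Target censoring proportion in `[0, 1)`.
#' @param seed Optional RNG seed.
#' @return An [outcome_spec] of kind `"survival"`.
#' @export
simulate_survival_outcome <- function(table, taxonomy = NULL,
                                      effect_taxon = NULL,
                                      effect_size = 0, censor_rate = 0,
                                      seed = NULL) {
  if (censor_rate < 0 || censor_rate >= 1) {
    abort("censor_rate must be in [0, 1)")
  }
  n <- nrow(table)
  x <- rep(0, n)
  if (!is.null(effect_taxon)) {
    if (is.null(taxonomy)) abort("effect_taxon requires a taxonomy")
    leaves <- leaf_descendants(taxonomy, effect_taxon)
    rel <- rowSums(table[, leaves, drop = FALSE]) / rowSums(table)
    s <- stats::sd(rel)
    x <- if (s > 0) (rel - mean(rel)) / s else rep(0, n)
  }
  rate <- exp(effect_size * x)
  draw <- function() {
    t_event <- rexp(n, rate = rate)
    if (censor_rate == 0) {
      return(list(time = t_event, event = rep(1, n)))
    }
    # uniform censoring window chosen so P(C < T) ~= censor_rate at the
    # average hazard: P(C < T) = (1 - exp(-r M)) / (r M) for C ~ U(0, M)
    r <- mean(rate)
    f <- function(mm) (1 - exp(-r * mm)) / (r * mm) - censor_rate
    mm <- stats::uniroot(f, c(1e-8, 1e6))$root
    c_time <- runif(n, 0, mm)
    list(time = pmin(t_event, c_time), event = as.numeric(t_event <= c_time))
  }
  out <- if (is.null(seed)) draw() else with_seed(seed, draw())
  outcome_spec("survival", values = out$time, event = out$event,
               sample_ids = rownames(table))
}
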