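---
title: "Conditional association testing for microbiome taxa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conditional association testing for microbiome taxa}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microcat)
```

## The model

Marginal differential-abundance tests ask whether a taxon's counts differ
between outcome groups on their own. Because microbiome features are
linked by taxonomy and phylogeny, marginal hits arrive in nested bundles,
and the level of the tree that actually carries outcome information is
obscured. The conditional question — does this taxon explain outcome
variation *not already captured by the other features*? — follows the
standard conditional-independence notion of a null feature: a feature is
null exactly when the outcome is independent of it given everything else.

The test statistic is the coefficient of determination of a global
association test on a beta-diversity distance matrix. For pairwise
distances $d_{ij}$, set $A = [-\tfrac12 d_{ij}^2]$ and Gower-center it,
$G = J A J$ with $J = I - \mathbf{1}\mathbf{1}'/n$. With $H$ the
orthogonal projector onto the column space of the design matrix (outcome
plus covariates, always including an intercept — which contributes
nothing to $\mathrm{tr}(HG)$ because $G$ is doubly centered),

$$SS_T = \mathrm{tr}(G), \qquad SS_A = \mathrm{tr}(HG), \qquad
R^2 = SS_A / SS_T.$$

The conditional test for a taxon $t$ with leaf set $\mathcal{L}(t)$
permutes, within each leaf column of $\mathcal{L}(t)$, the counts across
samples; recomputes the distance matrix and $R^2_b$ for each of $B$
permuted tables; and reports how often the permuted fit matches or beats
the original. Permutation destroys the sample alignment of exactly that
clade's counts while preserving every column's marginal distribution and
every other feature, so the drop in $R^2$ isolates the clade's *added*
explanatory value. The outcome is never permuted, and the outcome side of
the computation (design projector, or null-model residuals) is computed
once and reused for all $B$ datasets.

Two engines produce the $R^2$:

* **PERMANOVA** — the trace decomposition above. With covariates, the
  reported value is the sequential share
  $(\mathrm{tr}(H_{full}G) - \mathrm{tr}(H_{cov}G))/\mathrm{tr}(G)$ of
  the outcome fitted after the covariates.
* **Kernel score (MiRKAT-style)** — for continuous, binary and survival
  outcomes the variance-component score statistic $Q = r'Gr/2\phi$ of the
  null-model residuals $r$ (least-squares residuals; logistic residuals
  with $\phi = 1$; martingale residuals from a null Cox fit with
  $\phi = 1$). Because the score statistic is proportional to a
  coefficient of determination, we use the scale-free analogue
  $r^2 = r'Gr/(\mathrm{tr}(G)\, r'r)$ inside the permutation scheme. The
  proportionality constant is a convention; it cancels in the
  permutation comparison because $r$ and $\phi$ are fixed across the $B$
  datasets. When several distance metrics are supplied, the per-dataset
  statistic is the maximum $r^2$ over metrics, taken separately for the
  original and for each permuted dataset before comparing.

## Tie handling and the default p-value

The plain proportion $\hat p = \frac1B \sum_b I(R^2 - R^2_b < 0)$ (strict
inequality) returns $\hat p = 0$ for any taxon whose permutation cannot
change the distances at all — for example constant leaf columns — which
is the opposite of the correct degenerate answer. The default is
therefore the add-one, tie-inclusive estimator

$$\hat p = \frac{1 + \#\{R^2_b \ge R^2\}}{B + 1},$$

which is valid at finite $B$ ($P(\hat p \le \alpha) \le \alpha$ under the
null) and returns 1 for degenerate taxa. `tie_rule = "strict_paper"`
restores the strict proportion for exact comparability. Both behaviours
are asserted in the test suite.

## "By column": per-column versus joint permutation

Permuting "the elements of $\mathcal{L}(t)$ by column" can be read two
ways: an independent permutation per leaf column (destroying
within-clade correlation as well as sample alignment), or one shared row
permutation applied to the whole leaf block (preserving within-clade
correlation). Both are implemented; `permute_mode = "per_column"` is the
default and `"joint"` is available for sensitivity analysis. The
bookkeeping invariants — selected columns keep their multiset of values,
unselected columns are bit-identical, and under `"joint"` whole rows of
the block are preserved — are enforced by tests.

## Numerical choices

* The projector $H$ is computed from a pivoted QR of the design;
  rank-deficient designs are reduced by dropping dependent columns with a
  warning, so $H$ is always the projector onto the attained column
  space.
* When a design separates the samples perfectly, $SS_R$ lands at rounding
  error scale with arbitrary sign; it is clamped to zero (tolerance
  $10^{-12} \max(|SS_T|, 1)$) so the pseudo-F is $+\infty$ and ties with
  equally perfect permutations instead of producing a huge
  arbitrary-signed ratio.
* $G$ is *not* truncated to its positive-semidefinite part by default:
  CAT compares like with like across permuted datasets, and truncation
  would inject a nonlinearity. For semimetric distances $R^2$ can
  stray outside $[0,1]$ via negative eigenvalues; PCoA reports negative
  eigenvalues and omits their axes rather than clipping.
* Permutation p-values for the global PERMANOVA test also use the add-one
  correction.
* Unrooted Newick input is used as read, rooted at its basal polytomy;
  no midpoint re-rooting is attempted, so UniFrac values are
  deterministic but root-dependent, as usual.
* Weighted UniFrac defaults to the unnormalized variant
  ($\sum_b l_b |p_i(b) - p_j(b)|$, the common reference default); the
  normalized variant is a switch. Bray–Curtis and Jaccard are computed on
  raw counts / presence (no rarefaction anywhere: the permutation scheme
  operates on raw counts, and column permutation cannot create
  zero-total samples — a zero-total sample is therefore a hard input
  error, never silently dropped).
* UniFrac is computed from a precomputed leaf-by-branch incidence matrix
  so that the $B$ recomputations inside CAT reduce to one matrix product
  and one Manhattan-distance call per permuted table.
* Reproducibility: a single master seed yields per-taxon (and, in the
  simulation harness, per-dataset) substreams through a string-hash
  derivation, so results are independent of evaluation order and a taxon
  tested twice returns identical rows.

## The synthetic-data generator

The generator emulates a two-group 16S study: $n = 31$ samples per
group, sequencing depth 48,765 reads per sample, and per-sample
compositions drawn from a Dirichlet distribution whose concentration
parameters sum to $\theta = 62$ — a heavy-tailed, strongly overdispersed
regime typical of gut microbiome data. Counts are multinomial at fixed
depth; group differences are constructed by *spiking*: adding an
independent Poisson($\lambda$) draw to each leaf ASV of a chosen taxon in
group-1 samples (a `shared_draw` switch adds one draw per sample to all
spiked ASVs instead). Spiking is additive after the multinomial draw, so
group-0 totals equal the depth exactly and group-1 totals exceed it by
exactly the spike mass — an invariant the tests assert. $\lambda = 0$ is
the null scenario.

Because the real ecosystem behind such a study (its phylogeny, taxonomy
and marginal abundances) is external data, the generator substitutes:

* a random bifurcating tree with exponential(1) branch lengths whose
  seven-rank taxonomy is obtained by cutting the tree at nested
  depth quantiles (so every leaf has a complete lineage and clade sizes
  form a realistic ladder — a handful of phyla, a few dozen families at
  $m = 200$ leaves);
* a log-normal base composition with tunable skew. The default
  `skew_sigma = 3.5` was chosen once, using the generator's own
  achieved-skew report, to approximate the highly skewed family-abundance
  profile of real gut data (dominant family around 40–50 % of reads,
  median family share orders of magnitude smaller). With only ~200
  leaves the median family share cannot drop as low as in a
  1000-plus-ASV dataset while keeping the top share moderate; the
  scaled-down profile reproduces the *shape* (one dominant family, a
  long rare tail), not every decimal.

What passing tests on this generator do show: exact spike-mass
accounting, type-I error control and a null p-value distribution centred
near 0.5 at the reference conditions, and power that increases in
$\lambda$ and saturates for a mid-size (~3 % of reads) family. What they
cannot show: behaviour under real-data features the generator omits —
taxon-specific overdispersion, structural zeros beyond what the DM model
induces, compositional artefacts of variable sequencing depth, and
ecosystem-specific phylogenetic signal.

## Study sizes used in the checks

The calibration suite runs 100 null datasets (and the acceptance script
200) at the reference conditions with $B = 99$ permutations, and the
power check uses $\lambda \in \{0, 10, 70\}$ with 20 datasets each —
sizes chosen to keep the full suite a desk-scale computation while
leaving the binomial error on a rejection rate at a few percent.
Single-taxon analyses default to $B = 999$; the simulation harness uses
smaller $B$ because the rejection indicator, not the individual p-value,
is the quantity being averaged.

## Known limitations

* P-values are unadjusted; tree-structured multiplicity control across
  correlated conditional tests is out of scope, and ordinary
  Bonferroni/BH can be applied downstream at the caller's risk.
* The conditional null is approximated by unconditional column
  permutation: a taxon that is a weak, noisy shadow of a stronger clade
  is typically (and correctly) not rejected, but a shadow whose own
  sample alignment is strong relative to its permutation noise can still
  produce small p-values even though it is conditionally redundant in
  the strict sense.
* Features missing from the phylogenetic tree are an error, not silently
  pruned; the caller decides how to reconcile the data.
* The kernel engine's survival statistic uses martingale residuals from
  a null Cox fit; heavily tied event times inherit the usual Cox
  approximations.
```{r session}
sessionInfo()
```
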