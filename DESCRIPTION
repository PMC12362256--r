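Package: microcat
Title: Conditional Association Testing for Microbiome Taxa by Count Permutation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tests the conditional association between a microbiome taxon and
    an outcome by permuting the counts of the taxon's leaf-level features
    (ASVs/OTUs) and measuring the resulting drop in the coefficient of
    determination of a global association test. Supplies the surrounding
    machinery: Bray-Curtis, Jaccard, weighted and unweighted UniFrac
    beta-diversity distances; PERMANOVA sum-of-squares decomposition with
    covariate adjustment; kernel-machine (MiRKAT-style) score statistics for
    continuous, binary and survival outcomes; principal coordinates analysis;
    and a Dirichlet-multinomial spike-in simulator for power and
    type-I-error studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    phangorn,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    vegan
Suggests:
    jsonlite,
    optparse,
    phyloseq,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
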